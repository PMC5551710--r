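#' Binned log2 ratio of treatment over control
#'
#' Computes the per-bin log2(gammaH2A.X / H2A.X) ratio the domain caller
#' operates on. Each track is first scaled to counts-per-million of its own
#' library size (sequencing-depth normalisation), then
#' `log2((treat_cpm + p) / (control_cpm + p))` is taken per bin. With
#' `pseudocount = 0` (all bins positive) the operation is antisymmetric:
#' swapping the tracks negates the ratio.
#'
#' @param treat,control Count [binned_track()]s on the same bin grid, both
#'   with a positive `library_size`.
#' @param pseudocount Pseudocount in CPM units added inside the ratio to keep
#'   empty bins defined (default 1).
#' @return A `log2_ratio` [binned_track()].
#' @export
compute_log2_ratio <- function(treat, control, pseudocount = 1.0) {
  stopifnot(inherits(treat, "binned_track"), inherits(control, "binned_track"))
  stopifnot_same_grid(treat, control)
  if (is.null(treat$library_size) || is.null(control$library_size))
    stop("both tracks need a positive library_size for CPM scaling")
  if (pseudocount < 0) stop("`pseudocount` must be >= 0")
  chroms <- track_chroms(treat)
  vals <- lapply(chroms, function(ch) {
    t_cpm <- treat$values[[ch]] * 1e6 / treat$library_size
    c_cpm <- control$values[[ch]] * 1e6 / control$library_size
    log2((t_cpm + pseudocount) / (c_cpm + pseudocount))
  })
  names(vals) <- chroms
  binned_track(vals, treat$bin_size, "log2_ratio")
}

# Strict local maxima of one vector, plateau-aware: a run of equal values
# higher than both adjacent runs is one maximum, seeded at its leftmost bin.
# Runs touching the chromosome ends are never maxima. Returns 1-based indices.
local_maxima_runs <- function(v) {
  r <- rle(v)
  k <- length(r$lengths)
  if (k < 3L) return(integer(0))
  run_start <- cumsum(c(1L, r$lengths[-k]))
  j <- 2:(k - 1L)
  is_max <- r$values[j] > r$values[j - 1L] & r$values[j] > r$values[j + 1L]
  run_start[j][is_max]
}

#' Find peak seed bins on a log2-ratio track
#'
#' A bin is a seed iff it is a strict local maximum (greater than both
#' neighbours; plateaus are seeded at their leftmost bin), its value exceeds
#' `min_height`, and its prominence is at least `min_prominence`. Prominence
#' is the drop from the peak to the higher of its two flanking minima, where
#' each flanking minimum is the lowest value between the peak and the nearest
#' strictly higher value on that side (or the chromosome end), so minor
#' summits riding on a larger peak have small prominence while the summit of
#' an isolated domain keeps its full height over the surrounding baseline.
#'
#' The default selectivity, `"auto"`, is a quarter of the chromosome's value
#' range, mirroring common local-maxima detectors; at `min_prominence = 0`
#' the seeds are exactly the brute-force strict local maxima above
#' `min_height`.
#'
#' @param ratio A `log2_ratio` [binned_track()].
#' @param min_height Minimum seed value (default 0).
#' @param min_prominence Minimum prominence, or `"auto"` for (max - min)/4
#'   per chromosome.
#' @return Data.frame with columns `chrom`, `seed_bin` (0-based bin index)
#'   and `value`. Chromosomes shorter than 3 bins yield no seeds.
#' @export
find_peak_seeds <- function(ratio, min_height = 0.0, min_prominence = "auto") {
  stopifnot(inherits(ratio, "binned_track"))
  if (ratio$value_kind != "log2_ratio")
    stop("`ratio` must be a log2_ratio track")
  out <- lapply(track_chroms(ratio), function(ch) {
    v <- ratio$values[[ch]]
    if (length(v) < 3L) return(NULL)
    sel <- if (identical(min_prominence, "auto"))
      (max(v) - min(v)) / 4 else as.numeric(min_prominence)
    cand <- local_maxima_runs(v)
    if (length(cand) == 0L) return(NULL)
    n <- length(v)
    keep <- logical(length(cand))
    for (i in seq_along(cand)) {
      vi <- v[cand[i]]
      j <- cand[i] - 1L; left_min <- vi
      while (j >= 1L && v[j] <= vi) { left_min <- min(left_min, v[j]); j <- j - 1L }
      j <- cand[i] + 1L; right_min <- vi
      while (j <= n && v[j] <= vi) { right_min <- min(right_min, v[j]); j <- j + 1L }
      prom <- vi - max(left_min, right_min)
      keep[i] <- vi > min_height && prom >= sel
    }
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, seed_bin = cand[keep] - 1L, value = v[cand[keep]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(), seed_bin = integer(),
                      value = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Walk one direction from a seed (1-based index i1, step +1 or -1). Returns
# the 1-based index of the outermost retained bin: extension continues
# through runs of <= 0 bins shorter than stop_run; the first run reaching
# stop_run consecutive <= 0 bins terminates the walk and is excluded
# entirely. Hitting the chromosome end without such a run extends the
# domain to the boundary.
walk_extension <- function(v, i1, step, stop_run) {
  n <- length(v)
  last <- i1
  run <- 0L
  j <- i1 + step
  while (j >= 1L && j <= n) {
    if (v[j] <= 0) {
      run <- run + 1L
      if (run == stop_run) return(last)
    } else {
      run <- 0L
      last <- j
    }
    j <- j + step
  }
  if (step > 0L) n else 1L
}

#' Extend a seed bin into a damage domain
#'
#' Starting from a seed bin with positive ratio, the domain is extended left
#' and right independently until a run of `stop_run` consecutive bins with
#' value <= 0 is met (that terminating run is excluded entirely) or the
#' chromosome end is reached (the domain then runs to the boundary). Shorter
#' non-positive runs are traversed and retained inside the domain, so a
#' 7-bin gap does not split a domain when `stop_run = 8`. The result is
#' independent of which direction is walked first.
#'
#' @param ratio A `log2_ratio` [binned_track()].
#' @param chrom Chromosome name.
#' @param seed_bin 0-based seed bin index; its value must be > 0.
#' @param stop_run Number of consecutive non-positive bins that stops the
#'   extension (default 8).
#' @return One-row data.frame: `chrom`, `start`, `end` (bp, 0-based
#'   half-open, multiples of the bin size), `seed_bin`, `summit_value`.
#' @export
extend_domain <- function(ratio, chrom, seed_bin, stop_run = 8) {
  stopifnot(inherits(ratio, "binned_track"))
  v <- ratio$values[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  i1 <- as.integer(seed_bin) + 1L
  if (i1 < 1L || i1 > length(v)) stop("seed_bin out of range")
  if (v[i1] <= 0) stop("seed bin value must be > 0")
  left <- walk_extension(v, i1, -1L, stop_run)
  right <- walk_extension(v, i1, +1L, stop_run)
  data.frame(chrom = chrom,
             start = (left - 1L) * ratio$bin_size,
             end = right * ratio$bin_size,
             seed_bin = as.integer(seed_bin),
             summit_value = v[i1],
             stringsAsFactors = FALSE)
}

#' Call gammaH2A.X damage domains from a log2-ratio track
#'
#' Seeds from [find_peak_seeds()] are extended with [extend_domain()],
#' overlapping or identical domains are merged (union of the interval,
#' summit = the highest seed), and domains shorter than `min_length` bp are
#' discarded, so a 30-kb call is dropped and a 40-kb call retained at the
#' default. Returned domains never overlap and each contains at least one
#' positive bin (its summit).
#'
#' @inheritParams find_peak_seeds
#' @inheritParams extend_domain
#' @param min_length Minimum domain length in bp (default 40000); domains
#'   with `end - start < min_length` are removed.
#' @return Data.frame of domains sorted by coordinate: `chrom`, `start`,
#'   `end`, `seed_bin`, `summit_value`.
#' @export
call_damage_domains <- function(ratio, min_height = 0.0,
                                min_prominence = "auto",
                                stop_run = 8, min_length = 40000) {
  seeds <- find_peak_seeds(ratio, min_height, min_prominence)
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      seed_bin = integer(), summit_value = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(seeds) == 0L) return(empty)
  doms <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
    extend_domain(ratio, seeds$chrom[i], seeds$seed_bin[i], stop_run)
  }))
  merged <- lapply(split(doms, doms$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    out <- d[1, , drop = FALSE]
    for (i in seq_len(nrow(d))[-1]) {
      k <- nrow(out)
      if (d$start[i] < out$end[k]) {        # strict overlap (or identical)
        out$end[k] <- max(out$end[k], d$end[i])
        if (d$summit_value[i] > out$summit_value[k]) {
          out$summit_value[k] <- d$summit_value[i]
          out$seed_bin[k] <- d$seed_bin[i]
        }
      } else {
        out <- rbind(out, d[i, , drop = FALSE])
      }
    }
    out
  })
  doms <- do.call(rbind, merged)
  doms <- doms[doms$end - doms$start >= min_length, , drop = FALSE]
  doms <- doms[order(doms$chrom, doms$start), , drop = FALSE]
  rownames(doms) <- NULL
  doms
}

#' Write called domains as BED (summit value in the score column)
#' @param domains Data.frame from [call_damage_domains()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_domains_bed <- function(domains, file) {
  if (nrow(domains) == 0L) { writeLines(character(0), file); return(invisible(file)) }
  gr <- GenomicRanges::GRanges(domains$chrom,
                               IRanges::IRanges(domains$start + 1L, domains$end),
                               name = sprintf("domain_%03d", seq_len(nrow(domains))),
                               score = domains$summit_value)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
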