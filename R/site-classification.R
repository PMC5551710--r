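#' Summed log2-ratio signal in a window around one site
#'
#' Sums the values of all bins whose midpoint falls in
#' `[position - half_window, position + half_window)`; the window is
#' truncated at chromosome ends. Bin membership by midpoint is unambiguous
#' and never double-counts a partially overlapping bin: with 10-kb bins a
#' 50-kb window always contains exactly five bin midpoints, and shifting the
#' site without crossing a midpoint boundary leaves the value unchanged.
#'
#' @param ratio A `log2_ratio` [binned_track()].
#' @param chrom Chromosome name.
#' @param position 0-based site position in bp.
#' @param half_window Half-width of the window in bp (default 25000, i.e. the
#'   site +/- 25 kb).
#' @return The summed signal (0 for an all-zero track).
#' @export
window_signal <- function(ratio, chrom, position, half_window = 25000) {
  stopifnot(inherits(ratio, "binned_track"))
  v <- ratio$values[[chrom]]
  if (is.null(v)) stop("chromosome not in track: ", chrom)
  mids <- (seq_along(v) - 0.5) * ratio$bin_size
  sum(v[mids >= position - half_window & mids < position + half_window])
}

#' Score a site table against a ratio track
#'
#' Vectorised [window_signal()]: appends a `window_signal` column to a site
#' table. Scoring happens per site before any merging, so merging then
#' scoring and scoring then merging agree by construction.
#'
#' @param ratio A `log2_ratio` [binned_track()].
#' @param sites Data.frame with `chrom` and `start` columns.
#' @inheritParams window_signal
#' @return `sites` with a `window_signal` column.
#' @export
score_sites <- function(ratio, sites, half_window = 25000) {
  stopifnot(is.data.frame(sites))
  sites$window_signal <- vapply(seq_len(nrow(sites)), function(i) {
    window_signal(ratio, sites$chrom[i], sites$start[i], half_window)
  }, numeric(1))
  sites
}

#' Merge nearby sites into their best-scoring representative
#'
#' Consecutive same-chromosome sites closer than `min_gap` bp form
#' single-linkage clusters; each cluster is replaced by its member with the
#' highest `window_signal` (ties resolved to the leftmost member). Sites
#' exactly `min_gap` apart are NOT merged (the threshold is strict).
#'
#' @param scored Site data.frame with `chrom`, `start` and `window_signal`
#'   columns (see [score_sites()]).
#' @param min_gap Strict distance threshold in bp (default 10000).
#' @return The representative rows, ordered by coordinate, with an
#'   `n_merged` column giving each cluster's size.
#' @export
merge_nearby_sites <- function(scored, min_gap = 10000) {
  stopifnot(is.data.frame(scored),
            all(c("chrom", "start", "window_signal") %in% names(scored)))
  if (nrow(scored) == 0L) {
    scored$n_merged <- integer(0)
    return(scored)
  }
  scored <- scored[order(scored$chrom, scored$start), , drop = FALSE]
  reps <- lapply(split(scored, scored$chrom), function(d) {
    gap_new <- c(TRUE, diff(d$start) >= min_gap)
    cl <- cumsum(gap_new)
    do.call(rbind, lapply(split(d, cl), function(g) {
      r <- g[which.max(g$window_signal), , drop = FALSE]  # first max = leftmost
      r$n_merged <- nrow(g)
      r
    }))
  })
  out <- do.call(rbind, reps)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify sites as efficiently cut or uncut controls
#'
#' Sites overlapping a called damage domain are ranked by `window_signal`
#' (descending); the top `n_cut` are labelled `cut`. Among the remaining
#' non-domain sites, only genic ones (within the genic distance of a gene,
#' see [annotate_genic()]) are eligible as negative controls: the `n_control`
#' with the lowest `window_signal` are labelled `uncut_control`. Everything
#' else is `unclassified`. Ranking ties are broken to the leftmost
#' coordinate. If fewer candidates than requested exist, all are taken and a
#' warning records the actual counts.
#'
#' The labels partition the sites; the label set is invariant under uniform
#' positive rescaling of the ratio track (ranks are scale-free).
#'
#' @param scored Merged site data.frame with `chrom`, `start`,
#'   `window_signal` and logical `genic` columns.
#' @param domains Data.frame from [call_damage_domains()].
#' @param n_cut,n_control Number of cut and control labels to assign
#'   (defaults 200 each).
#' @return `scored` with logical `in_domain` and character `label` columns.
#' @export
classify_sites <- function(scored, domains, n_cut = 200, n_control = 200) {
  stopifnot(is.data.frame(scored))
  if (nrow(scored) == 0L) {
    scored$in_domain <- logical(0); scored$label <- character(0)
    return(scored)
  }
  if (!all(c("chrom", "start", "window_signal", "genic") %in% names(scored)))
    stop("`scored` needs columns chrom, start, window_signal, genic ",
         "(run score_sites() and annotate_genic() first)")
  in_dom <- logical(nrow(scored))
  for (i in seq_len(nrow(scored))) {
    d <- domains[domains$chrom == scored$chrom[i], , drop = FALSE]
    in_dom[i] <- any(scored$start[i] >= d$start & scored$start[i] < d$end)
  }
  scored$in_domain <- in_dom
  scored$label <- "unclassified"

  cut_cand <- which(in_dom)
  cut_cand <- cut_cand[order(-scored$window_signal[cut_cand],
                             scored$chrom[cut_cand], scored$start[cut_cand])]
  if (length(cut_cand) < n_cut)
    warning("only ", length(cut_cand), " in-domain candidate(s) for ", n_cut,
            " requested cut labels")
  scored$label[utils::head(cut_cand, n_cut)] <- "cut"

  ctl_cand <- which(!in_dom & scored$genic)
  ctl_cand <- ctl_cand[order(scored$window_signal[ctl_cand],
                             scored$chrom[ctl_cand], scored$start[ctl_cand])]
  if (length(ctl_cand) < n_control)
    warning("only ", length(ctl_cand), " genic non-domain candidate(s) for ",
            n_control, " requested control labels")
  scored$label[utils::head(ctl_cand, n_control)] <- "uncut_control"
  scored
}
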