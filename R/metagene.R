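#' Reference-point profile matrix around a site set
#'
#' One row per site, one column per `profile_bin`-sized cell across
#' `[position - half_width, position + half_width)`. Each cell holds the mean
#' per-bp coverage in its span, scaled to reads-per-million by
#' `1e6 / library_size`; bases beyond the chromosome ends contribute 0.
#' Column positions (bp offsets of the cell centres from the site) are stored
#' in the `"positions"` attribute.
#'
#' @param coverage A base-pair-resolution [binned_track()] (`bin_size = 1`).
#' @param sites Data.frame with `chrom` and `start` columns; rownames of the
#'   result follow the `name` column when present.
#' @param half_width Half-width W of the window in bp (default 5000).
#' @param profile_bin Cell width in bp (default 50); must divide
#'   `half_width`.
#' @param library_size Library size for RPM scaling; defaults to the track's
#'   own `library_size`.
#' @return A numeric matrix of class `profile_matrix` with attributes
#'   `positions`, `profile_bin` and `half_width`.
#' @export
build_profile_matrix <- function(coverage, sites, half_width = 5000,
                                 profile_bin = 50, library_size = NULL) {
  stopifnot(inherits(coverage, "binned_track"))
  if (coverage$bin_size != 1L)
    stop("`coverage` must be base-pair resolution (bin_size = 1)")
  if (nrow(sites) == 0L) stop("site set is empty")
  if (half_width %% profile_bin != 0)
    stop("`profile_bin` must divide `half_width`")
  if (is.null(library_size)) library_size <- coverage$library_size
  if (is.null(library_size)) stop("no library_size available for RPM scaling")
  ncell <- 2L * half_width %/% profile_bin
  cs <- lapply(coverage$values, function(v) c(0, cumsum(v)))
  mat <- matrix(0, nrow = nrow(sites), ncol = ncell)
  offsets <- -half_width + (seq_len(ncell) - 1L) * profile_bin
  for (i in seq_len(nrow(sites))) {
    ch <- sites$chrom[i]
    s <- cs[[ch]]
    if (is.null(s)) stop("chromosome not in coverage: ", ch)
    L <- length(s) - 1L
    lo <- sites$start[i] + offsets
    hi <- lo + profile_bin
    a <- pmin(pmax(lo, 0L), L)
    b <- pmin(pmax(hi, 0L), L)
    mat[i, ] <- (s[b + 1L] - s[a + 1L]) / profile_bin
  }
  mat <- mat * 1e6 / library_size
  rownames(mat) <- if ("name" %in% names(sites)) sites$name else NULL
  structure(mat,
            positions = -half_width + (seq_len(ncell) - 0.5) * profile_bin,
            profile_bin = profile_bin, half_width = half_width,
            class = c("profile_matrix", "matrix", "array"))
}

#' Per-position trimmed mean across sites
#'
#' At each position, the `floor(trim * n)` largest and smallest values across
#' sites are dropped and the rest averaged (so for a 100-site column with
#' `trim = 0.02`, two values are removed from each end).
#'
#' @param matrix A [build_profile_matrix()] result (or any sites x positions
#'   matrix) with at least 3 rows.
#' @param trim Fraction trimmed from each end, in [0, 0.5) (default 0.02).
#' @return Numeric vector of per-position trimmed means.
#' @export
trimmed_mean_profile <- function(matrix, trim = 0.02) {
  if (nrow(matrix) < 3L) stop("need at least 3 rows to trim")
  if (trim < 0 || trim >= 0.5) stop("`trim` must be in [0, 0.5)")
  apply(matrix, 2L, mean, trim = trim)
}

#' Centred rolling mean and SD
#'
#' Rolling statistics over windows of `window_bp / profile_bin` consecutive
#' entries; only full windows are reported (output length `n - w + 1`), so
#' the SD shadow is honest at the edges. Window `i` covers entries
#' `i .. i + w - 1` and is aligned to the window centre.
#'
#' @param values Numeric vector (e.g. a trimmed-mean profile).
#' @param window_bp Rolling window in bp (default 1000).
#' @param profile_bin Entry spacing in bp; `window_bp / profile_bin` must be
#'   a whole number w with `1 <= w <= length(values)`.
#' @param positions Optional bp positions of `values`; when given, window
#'   centre positions are returned.
#' @return List with `mean`, `sd` (sample SD; 0 for constant windows) and
#'   `position` (window centres, or centre indices when `positions` is NULL).
#' @export
rolling_stats <- function(values, window_bp = 1000, profile_bin = 50,
                          positions = NULL) {
  w <- window_bp / profile_bin
  if (w != as.integer(w) || w < 1L) stop("`window_bp / profile_bin` must be a positive integer")
  w <- as.integer(w)
  n <- length(values)
  if (w > n) stop("rolling window (", w, ") exceeds vector length (", n, ")")
  rmean <- zoo::rollmean(values, w)
  rsd <- if (w == 1L) rep(NA_real_, n) else zoo::rollapply(values, w, stats::sd)
  if (is.null(positions)) positions <- seq_len(n)
  centers <- zoo::rollmean(positions, w)
  list(mean = as.numeric(rmean), sd = as.numeric(rsd), position = as.numeric(centers))
}

#' Metagene profile around a site set
#'
#' Convenience wrapper: builds the profile matrix, takes the per-position
#' trimmed mean, and applies centred rolling mean/SD. The profile is reported
#' at all positions; the rolling curves only where a full window fits.
#'
#' @inheritParams build_profile_matrix
#' @inheritParams trimmed_mean_profile
#' @param roll_bp Rolling window in bp (default 1000).
#' @return List of class `metagene_profile`: `$profile` (data.frame
#'   `position`, `trimmed_mean`) and `$rolling` (data.frame `position`,
#'   `rolling_mean`, `rolling_sd`).
#' @export
metagene_profile <- function(coverage, sites, half_width = 5000,
                             profile_bin = 50, trim = 0.02, roll_bp = 1000,
                             library_size = NULL) {
  mat <- build_profile_matrix(coverage, sites, half_width, profile_bin, library_size)
  tm <- trimmed_mean_profile(mat, trim)
  pos <- attr(mat, "positions")
  rs <- rolling_stats(tm, roll_bp, profile_bin, positions = pos)
  structure(list(
    profile = data.frame(position = pos, trimmed_mean = tm),
    rolling = data.frame(position = rs$position, rolling_mean = rs$mean,
                         rolling_sd = rs$sd)
  ), class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  pk <- x$rolling$position[which.max(x$rolling$rolling_mean)]
  cat(sprintf("<metagene_profile> %d positions; rolling-mean peak at %+g bp\n",
              nrow(x$profile), pk))
  invisible(x)
}

#' Coverage sum in a fixed window around each site
#'
#' Sum of per-bp coverage over `[position - half, position + half)` for each
#' site, truncated at chromosome ends (a 1000-bp half-open window at the
#' default `half = 500`).
#'
#' @param coverage A base-pair-resolution [binned_track()].
#' @param sites Data.frame with `chrom` and `start` columns.
#' @param half Half-window in bp (default 500).
#' @param normalize If TRUE, scale sums to reads-per-million using the
#'   track's `library_size`.
#' @return Numeric vector, one sum per site.
#' @export
signal_sum_at_sites <- function(coverage, sites, half = 500, normalize = FALSE) {
  stopifnot(inherits(coverage, "binned_track"))
  if (coverage$bin_size != 1L)
    stop("`coverage` must be base-pair resolution (bin_size = 1)")
  cs <- lapply(coverage$values, function(v) c(0, cumsum(v)))
  out <- vapply(seq_len(nrow(sites)), function(i) {
    s <- cs[[sites$chrom[i]]]
    if (is.null(s)) stop("chromosome not in coverage: ", sites$chrom[i])
    L <- length(s) - 1L
    a <- min(max(sites$start[i] - half, 0L), L)
    b <- min(max(sites$start[i] + half, 0L), L)
    s[b + 1L] - s[a + 1L]
  }, numeric(1))
  if (normalize) {
    if (is.null(coverage$library_size)) stop("track has no library_size")
    out <- out * 1e6 / coverage$library_size
  }
  out
}

#' Per-site log2 ratio between two conditions
#'
#' `log2((plus + p) / (minus + p))` over aligned per-site signal vectors
#' (both already library-normalised), as used for boxplot-style comparison of
#' induced vs non-induced occupancy at cut and uncut site sets.
#'
#' @param plus,minus Aligned numeric vectors of per-site signal.
#' @param pseudocount Pseudocount added to both terms (default 1).
#' @return Numeric vector of per-site log2 ratios.
#' @export
site_condition_ratio <- function(plus, minus, pseudocount = 1.0) {
  if (length(plus) != length(minus))
    stop("`plus` and `minus` must have the same length")
  log2((plus + pseudocount) / (minus + pseudocount))
}
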