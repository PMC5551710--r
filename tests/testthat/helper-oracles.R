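# Independent brute-force oracles used across the suite. These deliberately
# recompute results the slow, obvious way and must never call the package
# functions they check.

# all 0-based start positions of motif in a sequence string, overlaps allowed
oracle_scan <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  hits <- integer(0)
  for (i in seq_len(n - m + 1L)) {
    if (substr(seq, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# interior strict local maxima of a numeric vector (1-based indices)
oracle_local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(vapply(2:(n - 1L), function(i) v[i] > v[i - 1L] && v[i] > v[i + 1L],
               logical(1))) + 1L
}

# extension boundaries by exhaustive scan of the consecutive-run rule:
# the first window of `run` consecutive bins <= 0 beyond the seed terminates
# that side and is excluded entirely; no such window reaches the chromosome end
oracle_extend <- function(v, seed1, run = 8L) {
  n <- length(v)
  right <- n
  if (seed1 < n) {
    for (j in (seed1 + 1L):n) {
      if (j + run - 1L > n) break
      if (all(v[j:(j + run - 1L)] <= 0)) { right <- j - 1L; break }
    }
  }
  left <- 1L
  if (seed1 > 1L) {
    for (j in (seed1 - 1L):1L) {
      if (j - run + 1L < 1L) break
      if (all(v[(j - run + 1L):j] <= 0)) { left <- j + 1L; break }
    }
  }
  c(left = left, right = right)
}

# transitive-closure clustering of positions with strict gap threshold
oracle_clusters <- function(pos, gap) {
  stopifnot(!is.unsorted(pos))
  cl <- integer(length(pos))
  cur <- 1L
  cl[1] <- cur
  for (i in seq_along(pos)[-1]) {
    if (pos[i] - pos[i - 1L] >= gap) cur <- cur + 1L
    cl[i] <- cur
  }
  cl
}

# naive rolling mean / sd over full windows
oracle_rolling <- function(v, w) {
  n <- length(v) - w + 1L
  list(mean = vapply(seq_len(n), function(i) mean(v[i:(i + w - 1L)]), numeric(1)),
       sd = vapply(seq_len(n), function(i) stats::sd(v[i:(i + w - 1L)]), numeric(1)))
}

# a small fast simulation config for unit tests; any field can be overridden
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_chromosomes = 2, chrom_length = 2e5, n_sites = 10,
         frac_cut = 0.3, min_site_gap = 12000, min_cut_gap = 30000,
         site_margin = 30000, domain_halfwidth = 25000, n_proteins = 200),
    list(...))
  do.call(simulation_config, args)
}

# log2-ratio track from plain per-chromosome vectors
ratio_track <- function(..., bin_size = 10000) {
  vals <- list(...)
  if (is.null(names(vals)) || any(!nzchar(names(vals))))
    names(vals) <- sprintf("chr%d", seq_along(vals))
  binned_track(vals, bin_size, "log2_ratio")
}
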