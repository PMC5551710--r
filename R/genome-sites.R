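#' Scan a genome for restriction-site motif occurrences
#'
#' Finds all forward-strand occurrences of a recognition motif, allowing
#' overlapping matches. AsiSI recognizes the palindromic 8-mer GCGATCGC, so a
#' forward scan is complete: the reverse-complement scan yields the identical
#' position set. Matching is case-insensitive; ambiguous bases (N) in the
#' subject never match.
#'
#' @param genome A named `Biostrings::DNAStringSet`, or a named character
#'   vector of sequences.
#' @param motif Recognition sequence, uppercase ACGT only. Default is the
#'   AsiSI site GCGATCGC.
#' @return A data.frame with columns `chrom`, `start` (0-based position of the
#'   first motif base) and `end` (half-open), one row per occurrence, ordered
#'   by chromosome then position.
#' @export
scan_restriction_sites <- function(genome, motif = "GCGATCGC") {
  if (!is.character(motif) || length(motif) != 1L || !nzchar(motif))
    stop("`motif` must be a single non-empty string")
  if (!grepl("^[ACGT]+$", motif))
    stop("`motif` must contain only uppercase A, C, G, T")
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet"))
    stop("`genome` must be a DNAStringSet or named character vector")
  if (is.null(names(genome)))
    stop("`genome` sequences must be named")
  hits <- lapply(seq_along(genome), function(i) {
    m <- Biostrings::matchPattern(motif, genome[[i]], fixed = TRUE)
    s0 <- BiocGenerics::start(m) - 1L  # 0-based
    if (length(s0) == 0L) return(NULL)
    data.frame(chrom = names(genome)[i], start = s0,
               end = s0 + nchar(motif), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Annotate sites with genic proximity
#'
#' A site is genic when the distance from its position to the nearest gene
#' interval is at most `max_dist` bp (0 when the position lies inside a gene).
#' All coordinates are 0-based half-open; for a site at position `p` and a
#' gene `[s, e)` the distance is `s - p` upstream, `p - e + 1` downstream and
#' 0 inside, so a site at 1000 is exactly 400 bp from a gene starting at 1400.
#'
#' Sites on chromosomes absent from the gene set are flagged non-genic with a
#' warning.
#'
#' @param sites Data.frame with columns `chrom` and `start` (0-based site
#'   position), e.g. from [scan_restriction_sites()].
#' @param genes Data.frame of gene intervals with columns `chrom`, `start`,
#'   `end` (0-based half-open). Ordering and duplication are irrelevant.
#' @param max_dist Maximum distance in bp for the genic call (default 500).
#' @return `sites` with a logical `genic` column appended (replaced if
#'   already present).
#' @export
annotate_genic <- function(sites, genes, max_dist = 500) {
  stopifnot(is.data.frame(sites), is.data.frame(genes))
  if (!all(c("chrom", "start") %in% names(sites)))
    stop("`sites` needs columns chrom, start")
  if (!all(c("chrom", "start", "end") %in% names(genes)))
    stop("`genes` needs columns chrom, start, end")
  genic <- logical(nrow(sites))
  missing_chroms <- setdiff(unique(sites$chrom), unique(genes$chrom))
  if (length(missing_chroms) > 0L && nrow(sites) > 0L)
    warning("no gene intervals on chromosome(s): ",
            paste(missing_chroms, collapse = ", "),
            "; their sites are flagged non-genic")
  for (ch in intersect(unique(sites$chrom), unique(genes$chrom))) {
    si <- which(sites$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    for (i in si) {
      p <- sites$start[i]
      d <- ifelse(p < g$start, g$start - p,
                  ifelse(p >= g$end, p - g$end + 1L, 0L))
      genic[i] <- min(d) <= max_dist
    }
  }
  sites$genic <- genic
  sites
}
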