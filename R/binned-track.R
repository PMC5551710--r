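#' Binned genomic signal track
#'
#' A `binned_track` holds one real-valued vector per chromosome at a fixed bin
#' width. It is the substrate of damage-domain calling: raw `count` tracks are
#' combined into a `log2_ratio` track by [compute_log2_ratio()], and per-bp
#' occupancy tracks are represented with `bin_size = 1`.
#'
#' The vector for a chromosome of length `L` has `ceiling(L / bin_size)`
#' entries; absent coverage is an explicit 0, never a missing value.
#'
#' @param values Named list of numeric vectors, one per chromosome.
#' @param bin_size Bin width in bp (1 for base-pair-resolution coverage).
#' @param value_kind `"count"` for raw binned read counts, `"log2_ratio"` for
#'   a ratio track.
#' @param library_size Total reads of the sequencing library the track was
#'   sampled from (counts only). Used for counts-per-million scaling.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size,
                         value_kind = c("count", "log2_ratio"),
                         library_size = NULL) {
  value_kind <- match.arg(value_kind)
  if (!is.list(values) || is.null(names(values)) || any(!nzchar(names(values))))
    stop("`values` must be a named list of numeric vectors (one per chromosome)")
  if (anyDuplicated(names(values)))
    stop("duplicated chromosome names in `values`")
  values <- lapply(values, as.numeric)
  if (any(vapply(values, anyNA, logical(1))))
    stop("binned tracks must not contain missing values (absent coverage is 0)")
  bin_size <- as.integer(bin_size)
  if (length(bin_size) != 1L || is.na(bin_size) || bin_size < 1L)
    stop("`bin_size` must be a single positive integer")
  if (!is.null(library_size)) {
    library_size <- as.numeric(library_size)
    if (length(library_size) != 1L || !is.finite(library_size) || library_size <= 0)
      stop("`library_size` must be a single positive number")
  }
  structure(
    list(values = values, bin_size = bin_size, value_kind = value_kind,
         library_size = library_size),
    class = "binned_track"
  )
}

#' @export
print.binned_track <- function(x, ...) {
  nb <- vapply(x$values, length, integer(1))
  cat(sprintf("<binned_track> %s, bin_size=%d, %d chromosome(s), %d bins total\n",
              x$value_kind, x$bin_size, length(nb), sum(nb)))
  if (!is.null(x$library_size))
    cat(sprintf("  library_size = %g\n", x$library_size))
  invisible(x)
}

#' Chromosome names of a track
#' @param track A [binned_track()].
#' @return Character vector of chromosome names.
#' @export
track_chroms <- function(track) names(track$values)

#' Chromosome lengths (bp) implied by a track
#' @param track A [binned_track()].
#' @return Named integer vector of lengths in bp.
#' @export
track_lengths <- function(track) {
  vapply(track$values, length, integer(1)) * track$bin_size
}

stopifnot_same_grid <- function(a, b) {
  if (a$bin_size != b$bin_size)
    stop("bin grid mismatch: bin sizes differ (", a$bin_size, " vs ", b$bin_size, ")")
  if (!identical(sort(names(a$values)), sort(names(b$values))))
    stop("bin grid mismatch: chromosome sets differ")
  la <- vapply(a$values, length, integer(1))
  lb <- vapply(b$values, length, integer(1))[names(la)]
  if (any(la != lb))
    stop("bin grid mismatch: chromosome lengths differ")
  invisible(TRUE)
}

#' Write a track as bedGraph
#'
#' Binned tracks (`bin_size > 1`) are written one line per bin; base-pair
#' tracks are run-length collapsed (standard bedGraph practice) to keep files
#' compact. Coordinates are 0-based half-open, as bedGraph requires.
#'
#' @param track A [binned_track()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_bedgraph <- function(track, file) {
  grl <- lapply(track_chroms(track), function(chrom) {
    v <- track$values[[chrom]]
    if (track$bin_size == 1L) {
      r <- rle(v)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends), score = r$values)
    } else {
      n <- length(v)
      starts <- (seq_len(n) - 1L) * track$bin_size + 1L
      GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, width = track$bin_size),
                             score = v)
    }
  })
  gr <- suppressWarnings(do.call(c, grl))
  rtracklayer::export(gr, file, format = "bedGraph")
  invisible(file)
}

#' Read a bedGraph file into a binned track
#'
#' Every bedGraph interval must align to the requested bin grid (its span is
#' assigned to all bins it fully covers). Bins without coverage become 0.
#'
#' @param file bedGraph path.
#' @param bin_size Bin width of the grid the file was written on.
#' @param chrom_lengths Optional named vector of chromosome lengths in bp;
#'   defaults to the largest end coordinate seen per chromosome.
#' @param value_kind,library_size Passed to [binned_track()].
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(file, bin_size, chrom_lengths = NULL,
                          value_kind = c("count", "log2_ratio"),
                          library_size = NULL) {
  value_kind <- match.arg(value_kind)
  gr <- rtracklayer::import(file, format = "bedGraph")
  chroms <- as.character(unique(GenomicRanges::seqnames(gr)))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) {
      max(GenomicRanges::end(gr[GenomicRanges::seqnames(gr) == ch]))
    }, numeric(1))
  }
  values <- lapply(chroms, function(ch) {
    L <- chrom_lengths[[ch]]
    nb <- ceiling(L / bin_size)
    v <- numeric(nb)
    sub <- gr[GenomicRanges::seqnames(gr) == ch]
    s0 <- GenomicRanges::start(sub) - 1L   # 0-based
    e0 <- GenomicRanges::end(sub)          # half-open end
    b1 <- s0 %/% bin_size + 1L
    b2 <- (e0 - 1L) %/% bin_size + 1L
    for (i in seq_along(sub)) v[b1[i]:b2[i]] <- S4Vectors::mcols(sub)$score[i]
    v
  })
  names(values) <- chroms
  binned_track(values, bin_size, value_kind, library_size)
}
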