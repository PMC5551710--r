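#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with validated
#' defaults. The defaults describe the study conditions the package's
#' validation suite runs under: a compact 4 x 1-Mb genome carrying 400
#' planted AsiSI recognition sites of which 12.5% are cut, plateau-shaped
#' gammaH2A.X damage domains of height 3 (log2 units over the background) and
#' half-width 25 kb over a Poisson(100) per-10-kb-bin background, a Dicer
#' occupancy bump planted 500 nt downstream of cut sites, and a
#' 2000-protein, paired-design intensity matrix with threefold effects in
#' 10% of proteins and logistic left-censoring around the 10% quantile.
#'
#' @param seed Integer RNG seed; each generator derives its own fixed
#'   sub-stream from it (seed, seed+1, ...).
#' @param n_chromosomes,chrom_length Genome shape; `chrom_length` must be a
#'   multiple of `bin_size`.
#' @param n_sites Number of planted motif occurrences genome-wide.
#' @param frac_cut Fraction of sites labelled cut, in [0,1];
#'   `frac_cut * n_sites >= 1`.
#' @param frac_genic Target fraction of sites placed within `genic_dist` of a
#'   simulated gene.
#' @param genic_dist Genic-proximity distance in bp (default 500).
#' @param min_site_gap Minimum distance between planted sites in bp (default
#'   10001, just above the 10-kb merge threshold so every planted site stays
#'   its own scoring unit).
#' @param site_margin Keep-out distance from chromosome ends for *cut*
#'   labels (default 30000, one bin beyond the domain support): cut sites
#'   are sampled only among sites at least
#'   this far from both ends, so planted damage domains are never truncated
#'   by a sequence boundary. Uncut sites may sit anywhere.
#' @param min_cut_gap Minimum distance between two cut sites (default
#'   55000 bp, beyond the domain support plus the scoring window). Real
#'   AsiSI-induced breaks are orders of magnitude sparser than the planted
#'   sites of this compact genome; without a spacing floor, overlapping
#'   enrichment plateaus would create signal configurations (an uncut site
#'   flanked by two sub-50-kb cut sites) that the real system does not
#'   produce and that no flanking-window ranking could resolve.
#' @param domain_halfwidth Damage-domain plateau half-width in bp (default
#'   25000, i.e. 50-kb domains).
#' @param domain_height Plateau height at cut sites, in log2 units over the
#'   background Poisson rate (default 3).
#' @param background_rate Expected background reads per bin (default 100).
#' @param bin_size Bin width in bp for the damage tracks (default 10000).
#' @param dicer_peak_offset Offset of the planted occupancy bump from cut
#'   sites in bp (default +500).
#' @param dicer_peak_height Relative height of the occupancy bump over the
#'   per-bp background (default 10, a strong ChIP peak).
#' @param dicer_peak_sd Gaussian SD of the bump in bp (default 150).
#' @param dicer_background Expected background coverage per bp (default 2).
#' @param n_proteins,n_pairs Size of the phospho matrix (proteins; paired
#'   replicates per condition, default 2 as in a duplicate paired design).
#' @param effect_fold Fold-change magnitude applied to affected proteins in
#'   the damage condition (default 3). Each affected protein is shifted by
#'   `+/- log2(effect_fold)` with a random sign, reflecting that a damage
#'   response contains both hyper- and hypo-phosphorylation; a one-sided
#'   shift would also violate the median-centring assumption of the
#'   normalisation by construction.
#' @param frac_affected Fraction of proteins carrying the effect (default
#'   0.1).
#' @param censor_quantile Per-sample quantile around which left-censoring
#'   operates, in [0, 1); 0 disables missingness.
#' @param censor_scale Logistic scale (log2 units) of the missingness curve
#'   (default 0.3); smaller values approach a hard threshold.
#' @param baseline_mean,baseline_sd Protein baseline log2 intensity
#'   distribution (defaults 25 and 3.5; protein intensity tables span
#'   several orders of magnitude, i.e. log2 SD well above the per-condition
#'   effect sizes).
#' @param replicate_sd Residual replicate noise SD in log2 units (default
#'   0.18, the precision scale of isotope-label paired quantification).
#' @param pair_sd SD of the shared per-pair (batch) offset (default 0.3);
#'   cancels in the paired design.
#' @param motif Planted recognition motif (default the AsiSI site GCGATCGC).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 4, chrom_length = 1e6,
                              n_sites = 400, frac_cut = 0.125,
                              frac_genic = 0.7, genic_dist = 500,
                              min_site_gap = 10001, site_margin = 30000,
                              min_cut_gap = 55000,
                              domain_halfwidth = 25000, domain_height = 3,
                              background_rate = 100, bin_size = 10000,
                              dicer_peak_offset = 500, dicer_peak_height = 10,
                              dicer_peak_sd = 150, dicer_background = 2,
                              n_proteins = 2000, n_pairs = 2,
                              effect_fold = 3.0, frac_affected = 0.1,
                              censor_quantile = 0.1, censor_scale = 0.3,
                              baseline_mean = 25, baseline_sd = 3.5,
                              replicate_sd = 0.18, pair_sd = 0.3,
                              motif = "GCGATCGC") {
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "chrom_length", "n_sites", "bin_size",
              "n_proteins", "n_pairs", "domain_halfwidth", "min_site_gap")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0)
      stop("`", nm, "` must be a single positive number")
  }
  if (cfg$frac_cut < 0 || cfg$frac_cut > 1) stop("`frac_cut` must be in [0, 1]")
  if (cfg$frac_cut * cfg$n_sites < 1) stop("`frac_cut * n_sites` must be >= 1")
  if (cfg$chrom_length %% cfg$bin_size != 0)
    stop("`chrom_length` must be divisible by `bin_size`")
  if (cfg$censor_quantile < 0 || cfg$censor_quantile >= 1)
    stop("`censor_quantile` must be in [0, 1)")
  if (!grepl("^[ACGT]+$", cfg$motif)) stop("`motif` must be uppercase ACGT")
  structure(cfg, class = "simulation_config")
}

# Distribute n sites over chromosomes as evenly as possible (deterministic).
sites_per_chrom <- function(n, k) {
  diff(floor(seq(0, n, length.out = k + 1)))
}

# Sample n positions in [lo, hi] with pairwise gaps >= gap.
place_positions <- function(n, lo, hi, gap) {
  if (n == 0L) return(integer(0))
  slack <- (hi - lo) - (n - 1) * gap
  if (slack < 0)
    stop("impossible site placement: ", n, " sites with minimum gap ", gap,
         " do not fit in ", hi - lo + 1, " bp")
  extra <- sort(stats::runif(n, 0, slack))
  as.integer(round(lo + extra + (seq_len(n) - 1) * gap))
}

#' Simulate a genome with planted restriction sites and genes
#'
#' Generates uniform-random A/C/G/T chromosomes with exactly `n_sites`
#' non-overlapping planted occurrences of the motif at recorded positions.
#' Accidental occurrences arising from the random background are removed by
#' rejection-resampling their bases (never touching a planted copy), so
#' [scan_restriction_sites()] recovers the planted list exactly. A random
#' `frac_cut` subset is labelled cut, and gene intervals (1-4 kb) are placed
#' so that a `frac_genic` fraction of sites lies within `genic_dist` of a
#' gene; gene lengths are capped well below `min_site_gap` so a gene planted
#' for one site can never make a neighbouring site genic, and the recorded
#' genic flag is exact.
#'
#' @param config A [simulation_config()].
#' @return List: `genome` (DNAStringSet), `sites` (data.frame `chrom`,
#'   `start`, `end`, `name`, logical `cut`, logical `genic`), `genes`
#'   (data.frame `chrom`, `start`, `end`, `name`). All coordinates 0-based
#'   half-open.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  motif <- strsplit(config$motif, "")[[1]]
  mlen <- length(motif)
  bases <- c("A", "C", "G", "T")
  L <- config$chrom_length
  margin <- min(config$site_margin, floor(L / 4))
  edge <- 1000L   # placement keep-out; cut labels use the larger `margin`
  per_chrom <- sites_per_chrom(config$n_sites, config$n_chromosomes)

  genome <- vector("list", config$n_chromosomes)
  site_rows <- list()
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    pos <- place_positions(per_chrom[ci], edge, L - edge - mlen,
                           config$min_site_gap)
    seqv <- sample(bases, L, replace = TRUE)
    for (p in pos) seqv[(p + 1):(p + mlen)] <- motif
    planted_bp <- unlist(lapply(pos, function(p) (p + 1):(p + mlen)))
    # rejection-resample accidental occurrences of the motif
    for (iter in 1:100) {
      found <- scan_chr_vector(seqv, config$motif)
      extra <- setdiff(found, pos)
      if (length(extra) == 0L) break
      for (p in extra) {
        span <- (p + 1):(p + mlen)
        editable <- setdiff(span, planted_bp)
        seqv[editable] <- sample(bases, length(editable), replace = TRUE)
      }
      if (iter == 100L) stop("motif rejection-resampling did not converge")
    }
    genome[[ci]] <- paste(seqv, collapse = "")
    if (length(pos) > 0L)
      site_rows[[ci]] <- data.frame(chrom = chrom, start = pos,
                                    end = pos + mlen, stringsAsFactors = FALSE)
  }
  names(genome) <- sprintf("chr%d", seq_len(config$n_chromosomes))
  sites <- do.call(rbind, site_rows)
  sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  sites$name <- sprintf("site_%04d", seq_len(nrow(sites)))
  n_cut <- round(config$frac_cut * nrow(sites))
  eligible <- which(sites$start >= margin &
                      sites$start <= L - margin - mlen)
  if (length(eligible) < n_cut)
    stop("impossible cut-site assignment: only ", length(eligible),
         " sites lie >= ", margin, " bp from chromosome ends")
  # cut labels on a spaced random subset: random anchor points with
  # guaranteed spacing, each snapped to the nearest unused eligible site
  # (snap error < min_site_gap on each side, covered by the anchor slack)
  cut_per_chrom <- sites_per_chrom(n_cut, config$n_chromosomes)
  # anchors leave room for the worst snap distance (half the largest
  # inter-site gap on each side, ~9 kb at the default density)
  anchor_gap <- config$min_cut_gap + 18000
  cut_idx <- integer(0)
  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%d", ci)
    el <- eligible[sites$chrom[eligible] == chrom]
    n_c <- cut_per_chrom[ci]
    if (n_c == 0L) next
    anchors <- place_positions(n_c, margin, L - margin - mlen, anchor_gap)
    picked <- integer(0)
    for (a in anchors) {
      free <- setdiff(el, picked)
      picked <- c(picked, free[which.min(abs(sites$start[free] - a))])
    }
    if (length(picked) < n_c ||
        (n_c > 1L && min(diff(sort(sites$start[picked]))) < config$min_cut_gap))
      stop("impossible cut-site assignment: could not place ", n_c,
           " cut sites with min_cut_gap = ", config$min_cut_gap,
           " on ", chrom)
    cut_idx <- c(cut_idx, picked)
  }
  sites$cut <- FALSE
  sites$cut[cut_idx] <- TRUE

  # gene placement: overlap or lie just downstream of designated genic sites
  n_genic <- round(config$frac_genic * nrow(sites))
  genic_idx <- sort(sample.int(nrow(sites), n_genic))
  gene_rows <- lapply(genic_idx, function(i) {
    glen <- sample(1000:4000, 1L)
    p <- sites$start[i]
    if (stats::runif(1) < 0.5) {
      gstart <- p - sample.int(glen - mlen, 1L)        # gene spans the site
    } else {
      gstart <- p + sample.int(config$genic_dist, 1L)  # site just upstream
    }
    gstart <- max(gstart, 0)
    data.frame(chrom = sites$chrom[i], start = gstart,
               end = min(gstart + glen, L), stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, gene_rows)
  if (is.null(genes))
    genes <- data.frame(chrom = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) > 0L) genes$name <- sprintf("gene_%04d", seq_len(nrow(genes)))
  sites$genic <- FALSE
  sites$genic[genic_idx] <- TRUE

  list(genome = Biostrings::DNAStringSet(unlist(genome)),
       sites = sites, genes = genes)
}

# Fast motif scan of a character vector; returns 0-based start positions.
scan_chr_vector <- function(seqv, motif) {
  m <- strsplit(motif, "")[[1]]
  idx <- which(seqv == m[1])
  idx <- idx[idx + length(m) - 1L <= length(seqv)]
  for (k in seq_along(m)[-1]) {
    idx <- idx[seqv[idx + k - 1L] == m[k]]
    if (length(idx) == 0L) break
  }
  idx - 1L
}

#' Simulate binned gammaH2A.X / H2A.X damage tracks
#'
#' H2A.X bins are Poisson(`background_rate`); gammaH2A.X bins are
#' Poisson(`background_rate * 2^e(b)`) where `e(b)` is a plateau of height
#' `domain_height` over `position +/- domain_halfwidth` around each cut site
#' (bin membership by midpoint; overlapping plateaus saturate at the
#' plateau height) and 0 elsewhere. Uncut sites receive no enrichment.
#' Library sizes are the realised total counts, so depth normalisation in
#' [compute_log2_ratio()] reflects the enrichment burden of the gammaH2A.X
#' library, as it does for real ChIP libraries.
#'
#' @param sites Site table with `chrom`, `start` and logical `cut` columns
#'   (from [simulate_genome()]).
#' @param config A [simulation_config()].
#' @param chrom_lengths Optional named lengths in bp; defaults to
#'   `n_chromosomes` x `chrom_length` from the config.
#' @return List of two count [binned_track()]s: `gamma` and `h2ax`.
#' @export
simulate_damage_tracks <- function(sites, config, chrom_lengths = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(
      rep(config$chrom_length, config$n_chromosomes),
      sprintf("chr%d", seq_len(config$n_chromosomes)))
  }
  gamma <- list(); h2ax <- list()
  for (ch in names(chrom_lengths)) {
    nb <- ceiling(chrom_lengths[[ch]] / config$bin_size)
    mids <- (seq_len(nb) - 0.5) * config$bin_size
    e <- numeric(nb)
    cut_pos <- sites$start[sites$chrom == ch & sites$cut]
    for (p in cut_pos) {
      sel <- mids >= p - config$domain_halfwidth &
        mids < p + config$domain_halfwidth
      e[sel] <- config$domain_height
    }
    gamma[[ch]] <- stats::rpois(nb, config$background_rate * 2^e)
    h2ax[[ch]] <- stats::rpois(nb, config$background_rate)
  }
  list(
    gamma = binned_track(gamma, config$bin_size, "count",
                         library_size = sum(unlist(gamma))),
    h2ax = binned_track(h2ax, config$bin_size, "count",
                        library_size = sum(unlist(h2ax)))
  )
}

#' Simulate base-pair-resolution Dicer occupancy tracks
#'
#' The non-induced (`minus`) track is Poisson background everywhere. In the
#' induced (`plus`) track, each cut site additionally carries a Gaussian
#' occupancy bump of relative height `dicer_peak_height` and SD
#' `dicer_peak_sd`, centred `dicer_peak_offset` bp downstream of the site
#' (emulating occupancy peaking ~500 nt from the break). Uncut sites get no
#' bump in either condition.
#'
#' @inheritParams simulate_damage_tracks
#' @return List of two per-bp count [binned_track()]s: `plus` (induced) and
#'   `minus` (non-induced), with realised library sizes.
#' @export
simulate_dicer_coverage <- function(sites, config, chrom_lengths = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats::setNames(
      rep(config$chrom_length, config$n_chromosomes),
      sprintf("chr%d", seq_len(config$n_chromosomes)))
  }
  plus <- list(); minus <- list()
  for (ch in names(chrom_lengths)) {
    L <- as.integer(chrom_lengths[[ch]])
    lam <- rep(config$dicer_background, L)
    cut_pos <- sites$start[sites$chrom == ch & sites$cut]
    reach <- ceiling(4 * config$dicer_peak_sd)
    for (p in cut_pos) {
      center <- p + config$dicer_peak_offset
      idx <- max(1L, center - reach + 1L):min(L, center + reach + 1L)
      x <- (idx - 1L) - center
      lam[idx] <- lam[idx] + config$dicer_background * config$dicer_peak_height *
        exp(-x^2 / (2 * config$dicer_peak_sd^2))
    }
    plus[[ch]] <- stats::rpois(L, lam)
    minus[[ch]] <- stats::rpois(L, config$dicer_background)
  }
  list(
    plus = binned_track(plus, 1L, "count", library_size = sum(unlist(plus))),
    minus = binned_track(minus, 1L, "count", library_size = sum(unlist(minus)))
  )
}

#' Simulate a paired phospho intensity matrix with left-censored missingness
#'
#' True log2 intensities are `baseline + pair offset + condition effect +
#' replicate noise`; a `frac_affected` subset of proteins is shifted up by
#' `log2(effect_fold)` in the damage condition. Missingness is
#' missing-not-at-random: per sample, values go missing with logistic
#' probability `plogis((c_j - x) / censor_scale)` where `c_j` is that
#' sample's `censor_quantile` quantile of the complete data, so the missing
#' probability is non-increasing in intensity. `censor_quantile = 0`
#' disables missingness entirely.
#'
#' @param config A [simulation_config()].
#' @return List: `intensities` (raw-scale matrix with NAs, samples named
#'   `<condition>_<pair>`), `log_complete` (complete log2 matrix),
#'   `condition`, `pair`, `affected` (logical ground truth), `direction`
#'   (-1/0/+1 per protein: the sign of the planted shift), and
#'   `censor_points` (per-sample log2 thresholds; NA when disabled).
#' @export
simulate_phospho_matrix <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_pairs < 2L) stop("need n_pairs >= 2")
  set.seed(config$seed + 3L)
  n <- config$n_proteins
  k <- config$n_pairs
  condition <- rep(c("control", "damage"), each = k)
  pair <- as.character(rep(seq_len(k), times = 2))
  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  affected <- rep(FALSE, n)
  affected[sample.int(n, round(config$frac_affected * n))] <- TRUE
  direction <- ifelse(stats::runif(n) < 0.5, -1, 1) * affected
  pair_off <- matrix(stats::rnorm(n * k, 0, config$pair_sd), n, k)
  eff <- direction * log2(config$effect_fold)
  logm <- matrix(0, n, 2L * k,
                 dimnames = list(sprintf("protein_%05d", seq_len(n)),
                                 paste(condition, pair, sep = "_")))
  for (j in seq_len(2L * k)) {
    shift <- if (condition[j] == "damage") eff else 0
    logm[, j] <- baseline + pair_off[, as.integer(pair[j])] + shift +
      stats::rnorm(n, 0, config$replicate_sd)
  }
  censor_points <- rep(NA_real_, 2L * k)
  obs <- logm
  if (config$censor_quantile > 0) {
    for (j in seq_len(2L * k)) {
      cj <- stats::quantile(logm[, j], config$censor_quantile, names = FALSE)
      pmiss <- stats::plogis((cj - logm[, j]) / config$censor_scale)
      obs[stats::runif(n) < pmiss, j] <- NA
      censor_points[j] <- cj
    }
  }
  list(intensities = 2^obs, log_complete = logm, condition = condition,
       pair = pair, affected = affected, direction = direction,
       censor_points = censor_points)
}

#' Write simulated sites or genes as BED
#'
#' Sites are written as BED6 with the cut truth label (0/1) in the score
#' column and `genic=` encoded in the name; genes as BED4.
#'
#' @param sites,genes Tables from [simulate_genome()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_sites_bed <- function(sites, file) {
  name <- sites$name
  if ("genic" %in% names(sites))
    name <- sprintf("%s|genic=%d", name, as.integer(sites$genic))
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$start + 1L, sites$end),
                               name = name,
                               score = if ("cut" %in% names(sites))
                                 as.integer(sites$cut) else 0L)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' @rdname write_sites_bed
#' @export
write_genes_bed <- function(genes, file) {
  gr <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1L, genes$end),
                               name = genes$name)
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}

#' Read a sites BED written by [write_sites_bed()]
#' @param file BED path.
#' @return Site data.frame with `chrom`, `start`, `end`, `name`, `cut`,
#'   `genic` columns.
#' @export
read_sites_bed <- function(file) {
  gr <- rtracklayer::import(file, format = "BED")
  nm <- S4Vectors::mcols(gr)$name
  genic <- grepl("\\|genic=1$", nm)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = sub("\\|genic=[01]$", "", nm),
             cut = S4Vectors::mcols(gr)$score == 1,
             genic = genic,
             stringsAsFactors = FALSE)
}
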