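#' Pipeline configuration
#'
#' All procedural constants of the analysis chain in one validated list: the
#' simulation knobs (see [simulation_config()]) plus the analysis parameters
#' (10-kb bins, the 8-bin extension stop rule, the 40-kb minimum domain
#' length, the +/-25-kb scoring window, the strict <10-kb site merge, 200 cut
#' / 200 control labels, 500-nt genic distance, 2% trim, 1-kb rolling window,
#' +/-500-nt signal sums, QRILC tune 1.0). Everything can be overridden;
#' the configuration survives a serialisation round-trip (e.g. via
#' [utils::write.table()]/`dput`) unchanged.
#'
#' @param seed Integer seed governing every stochastic stage.
#' @param n_cut,n_control Cut / uncut-control label counts.
#' @param half_window Site-scoring half-window in bp.
#' @param min_gap Strict site-merge threshold in bp.
#' @param stop_run Consecutive non-positive bins terminating domain
#'   extension.
#' @param min_length Minimum domain length in bp.
#' @param min_height,min_prominence Seed thresholds, see
#'   [find_peak_seeds()].
#' @param pseudocount CPM pseudocount of the ratio track.
#' @param trim Metagene trim fraction.
#' @param roll Rolling window in bp.
#' @param profile_half_width,profile_bin Metagene matrix extent and cell
#'   size in bp.
#' @param sum_half Half-window of per-site signal sums in bp.
#' @param tune QRILC sigma multiplier.
#' @param qvalue_B Bootstrap resamples for pi0.
#' @param ... Overrides forwarded to [simulation_config()] (e.g. `n_sites`,
#'   `frac_cut`, `effect_fold`).
#' @return List of class `pipeline_config` with elements `sim` (the
#'   simulation config) and the analysis parameters.
#' @export
pipeline_config <- function(seed = 1, n_cut = 200, n_control = 200,
                            half_window = 25000, min_gap = 10000,
                            stop_run = 8, min_length = 40000,
                            min_height = 0, min_prominence = "auto",
                            pseudocount = 1, trim = 0.02, roll = 1000,
                            profile_half_width = 5000, profile_bin = 50,
                            sum_half = 500, tune = 1.0, qvalue_B = 100, ...) {
  params <- list(seed = seed, n_cut = n_cut, n_control = n_control,
                 half_window = half_window, min_gap = min_gap,
                 stop_run = stop_run, min_length = min_length,
                 min_height = min_height, min_prominence = min_prominence,
                 pseudocount = pseudocount, trim = trim, roll = roll,
                 profile_half_width = profile_half_width,
                 profile_bin = profile_bin, sum_half = sum_half,
                 tune = tune, qvalue_B = qvalue_B)
  numeric_pos <- c("n_cut", "n_control", "half_window", "min_gap", "stop_run",
                   "min_length", "trim", "roll", "profile_half_width",
                   "profile_bin", "sum_half", "tune", "qvalue_B")
  for (nm in setdiff(numeric_pos, "trim")) {
    if (!is.numeric(params[[nm]]) || params[[nm]] <= 0)
      stop("`", nm, "` must be positive")
  }
  params$sim <- simulation_config(seed = seed, ...)
  structure(params, class = "pipeline_config")
}

#' Write a FASTA genome
#' @param genome A named `DNAStringSet`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_genome_fasta <- function(genome, file) {
  Biostrings::writeXStringSet(genome, file)
  invisible(file)
}

write_tsv <- function(d, file) {
  utils::write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Run the full simulate-to-results workflow
#'
#' Executes every stage from one seed and writes all outputs under
#' `out_dir`: simulate genome/sites/genes, damage tracks, log2 ratio,
#' domain calls, site scan + genic annotation + scoring + merge +
#' classification, Dicer metagene profile and +/-500-nt condition ratios,
#' and the phospho pipeline. A `manifest.tsv` records every file with its
#' row count and MD5 checksum; the same seed yields byte-identical outputs,
#' and a deleted intermediate is regenerated identically on rerun.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress (default TRUE).
#' @return Invisibly, a list with the in-memory results of every stage plus
#'   `manifest` (data.frame `file`, `n_rows`, `md5`).
#' @export
run_end_to_end <- function(config = pipeline_config(), out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)
  pth <- function(f) file.path(out_dir, f)
  manifest <- list()
  note <- function(file, n) manifest[[length(manifest) + 1L]] <<-
    data.frame(file = basename(file), n_rows = n, stringsAsFactors = FALSE)

  say("simulating genome and sites ...")
  sim <- simulate_genome(config$sim)
  write_genome_fasta(sim$genome, pth("genome.fa")); note(pth("genome.fa"), length(sim$genome))
  write_sites_bed(sim$sites, pth("sites.bed"));     note(pth("sites.bed"), nrow(sim$sites))
  write_genes_bed(sim$genes, pth("genes.bed"));     note(pth("genes.bed"), nrow(sim$genes))

  say("simulating damage tracks and computing log2 ratio ...")
  tracks <- simulate_damage_tracks(sim$sites, config$sim)
  write_bedgraph(tracks$gamma, pth("gammaH2AX.bedGraph"))
  note(pth("gammaH2AX.bedGraph"), sum(vapply(tracks$gamma$values, length, integer(1))))
  write_bedgraph(tracks$h2ax, pth("H2AX.bedGraph"))
  note(pth("H2AX.bedGraph"), sum(vapply(tracks$h2ax$values, length, integer(1))))
  ratio <- compute_log2_ratio(tracks$gamma, tracks$h2ax, config$pseudocount)
  write_bedgraph(ratio, pth("ratio.bedGraph"))
  note(pth("ratio.bedGraph"), sum(vapply(ratio$values, length, integer(1))))

  say("calling damage domains ...")
  domains <- call_damage_domains(ratio, config$min_height, config$min_prominence,
                                 config$stop_run, config$min_length)
  write_domains_bed(domains, pth("domains.bed")); note(pth("domains.bed"), nrow(domains))

  say("scanning, scoring and classifying sites ...")
  scanned <- scan_restriction_sites(sim$genome, config$sim$motif)
  scanned <- annotate_genic(scanned, sim$genes, config$sim$genic_dist)
  scored <- score_sites(ratio, scanned, config$half_window)
  merged <- merge_nearby_sites(scored, config$min_gap)
  classified <- suppressWarnings(
    classify_sites(merged, domains, config$n_cut, config$n_control))
  write_tsv(classified, pth("classified_sites.tsv"))
  note(pth("classified_sites.tsv"), nrow(classified))

  say("building Dicer metagene profile and site ratios ...")
  dicer <- simulate_dicer_coverage(sim$sites, config$sim)
  cut_sites <- sim$sites[sim$sites$cut, , drop = FALSE]
  uncut_sites <- sim$sites[!sim$sites$cut, , drop = FALSE]
  prof <- metagene_profile(dicer$plus, cut_sites,
                           half_width = config$profile_half_width,
                           profile_bin = config$profile_bin,
                           trim = config$trim, roll_bp = config$roll)
  prof_df <- merge(prof$profile, prof$rolling, by = "position", all = TRUE)
  prof_df <- prof_df[order(prof_df$position), , drop = FALSE]
  write_tsv(prof_df, pth("metagene_profile.tsv")); note(pth("metagene_profile.tsv"), nrow(prof_df))
  all_sites <- rbind(cut_sites, uncut_sites)
  sums_plus <- signal_sum_at_sites(dicer$plus, all_sites, config$sum_half, normalize = TRUE)
  sums_minus <- signal_sum_at_sites(dicer$minus, all_sites, config$sum_half, normalize = TRUE)
  ratios <- data.frame(site = all_sites$name, cut = all_sites$cut,
                       sum_plus = sums_plus, sum_minus = sums_minus,
                       log2_ratio = site_condition_ratio(sums_plus, sums_minus),
                       stringsAsFactors = FALSE)
  write_tsv(ratios, pth("site_condition_ratios.tsv")); note(pth("site_condition_ratios.tsv"), nrow(ratios))

  say("running phospho pipeline ...")
  ph_sim <- simulate_phospho_matrix(config$sim)
  write_phospho_tsv(ph_sim$intensities, ph_sim$condition, ph_sim$pair,
                    pth("phospho_matrix.tsv"))
  note(pth("phospho_matrix.tsv"), nrow(ph_sim$intensities))
  ph <- run_phospho_pipeline(ph_sim$intensities, ph_sim$condition, ph_sim$pair,
                             seed = config$seed + 4L, tune = config$tune,
                             B = config$qvalue_B)
  write_tsv(ph$results, pth("phospho_results.tsv")); note(pth("phospho_results.tsv"), nrow(ph$results))

  manifest <- do.call(rbind, manifest)
  manifest$md5 <- unname(tools::md5sum(file.path(out_dir, manifest$file)))
  write_tsv(manifest, pth("manifest.tsv"))
  say("done: ", nrow(manifest), " files in ", out_dir)
  invisible(list(sim = sim, tracks = tracks, ratio = ratio, domains = domains,
                 classified = classified, dicer_profile = prof, ratios = ratios,
                 phospho = ph, manifest = manifest))
}
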