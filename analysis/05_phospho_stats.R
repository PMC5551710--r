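#!/usr/bin/env Rscript
# Stage 5: protein-level phosphoproteomics statistics.
#
# Runs the full chain on the simulated intensity matrix: log2 + median/MAD
# normalisation, missingness filter, one-missing imputation, QRILC
# truncated-normal imputation, per-column re-centring, paired t-tests and
# bootstrap-pi0 q-values. The default duplicate design (2 pairs) mirrors the
# paired experiment; a 4-pair variant shows the power the same pipeline
# reaches with more replicates.

library(dsbpipe)

dir.create("results", showWarnings = FALSE)
dir.create("scratch/analysis", recursive = TRUE, showWarnings = FALSE)

run_one <- function(n_pairs) {
  cfg <- simulation_config(seed = 1, n_pairs = n_pairs)
  ps <- simulate_phospho_matrix(cfg)
  res <- run_phospho_pipeline(ps$intensities, ps$condition, ps$pair,
                              seed = 1000 + n_pairs, verbose = TRUE)
  truth <- rownames(ps$intensities)[ps$affected]
  disc <- res$results$protein[res$results$q < 0.05]
  list(res = res,
       recall = length(intersect(disc, truth)) / length(truth),
       fdr = if (length(disc)) length(setdiff(disc, truth)) / length(disc) else 0,
       ndisc = length(disc))
}

message("-- duplicate design (2 pairs, as in the paired experiment) --")
two <- run_one(2)
message("-- extended design (4 pairs) --")
four <- run_one(4)

write.table(four$res$results, "scratch/analysis/05_phospho_results_full.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
top <- four$res$results[four$res$results$q < 0.1, ]
write.table(top[order(top$q), ], "results/05_phospho_top_hits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

summary <- data.frame(
  design = c("2 pairs", "4 pairs"),
  tested = c(nrow(two$res$results), nrow(four$res$results)),
  pi0 = round(c(two$res$pi0, four$res$pi0), 3),
  discoveries_q05 = c(two$ndisc, four$ndisc),
  recall = round(c(two$recall, four$recall), 3),
  observed_fdr = round(c(two$fdr, four$fdr), 3))
write.table(summary, "results/05_phospho_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("With 2 pairs (df = 1) the paired t-test has essentially no power at ",
        "q < 0.05 (", two$ndisc, " discoveries); with 4 pairs the same ",
        "pipeline recovers ", round(100 * four$recall, 1),
        "% of affected proteins at observed FDR ",
        round(four$fdr, 3), ".")
message("Summaries in results/05_phospho_summary.tsv; full table under scratch/analysis/.")
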