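#!/usr/bin/env Rscript
# Stage 4: Dicer occupancy around cut sites.
#
# Builds the reference-point profile matrix over the cut-site set
# (+/-5 kb, 50-bp cells, RPM-normalised), summarises it with a 2%-trimmed
# mean and a 1-kb rolling mean/SD, and contrasts +/-500-nt signal sums
# between induced and non-induced conditions at cut vs uncut sites.

library(dsbpipe)

cfg <- pipeline_config(seed = 1)
dir.create("results", showWarnings = FALSE)

sim <- simulate_genome(cfg$sim)
dicer <- simulate_dicer_coverage(sim$sites, cfg$sim)
cut <- sim$sites[sim$sites$cut, ]

prof <- metagene_profile(dicer$plus, cut,
                         half_width = cfg$profile_half_width,
                         profile_bin = cfg$profile_bin,
                         trim = cfg$trim, roll_bp = cfg$roll)
prof_df <- merge(prof$profile, prof$rolling, by = "position", all = TRUE)
write.table(prof_df[order(prof_df$position), ],
            "results/04_metagene_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

peak <- prof$rolling$position[which.max(prof$rolling$rolling_mean)]

sp <- signal_sum_at_sites(dicer$plus, sim$sites, cfg$sum_half, normalize = TRUE)
sm <- signal_sum_at_sites(dicer$minus, sim$sites, cfg$sum_half, normalize = TRUE)
r <- site_condition_ratio(sp, sm)
w <- wilcox.test(r[sim$sites$cut], r[!sim$sites$cut], alternative = "greater")

ratio_summary <- data.frame(
  metric = c("rolling_peak_offset_bp", "median_ratio_cut",
             "median_ratio_uncut", "wilcoxon_p_one_sided"),
  value = c(peak, round(median(r[sim$sites$cut]), 4),
            round(median(r[!sim$sites$cut]), 4),
            signif(w$p.value, 4)))
write.table(ratio_summary, "results/04_site_ratio_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Rolling-mean occupancy over cut sites peaks at ", peak,
        " bp from the site (planted at +", cfg$sim$dicer_peak_offset, ").")
message("Induced/non-induced log2 ratio medians: cut ",
        ratio_summary$value[2], " vs uncut ", ratio_summary$value[3],
        " (one-sided Wilcoxon p = ", ratio_summary$value[4], ").")
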