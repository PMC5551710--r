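#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs from one seed.
#
# Emulated system: an AsiSI-ER cell line in which 4OHT induction creates
# sequence-specific double-strand breaks at a subset of GCGATCGC sites,
# gammaH2A.X spreads in broad domains around the cut sites, Dicer occupancy
# peaks ~500 nt from them, and the damage response shifts a fraction of the
# phosphoproteome threefold.
#
# Bulky raw inputs (FASTA, bedGraphs, intensity matrix) go to scratch/inputs;
# results/ receives a small summary table.

library(dsbpipe)

cfg <- pipeline_config(seed = 1)
dir.create("scratch/inputs", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

sim <- simulate_genome(cfg$sim)
tracks <- simulate_damage_tracks(sim$sites, cfg$sim)
phospho <- simulate_phospho_matrix(cfg$sim)

write_genome_fasta(sim$genome, "scratch/inputs/genome.fa")
write_sites_bed(sim$sites, "scratch/inputs/sites.bed")
write_genes_bed(sim$genes, "scratch/inputs/genes.bed")
write_bedgraph(tracks$gamma, "scratch/inputs/gammaH2AX.bedGraph")
write_bedgraph(tracks$h2ax, "scratch/inputs/H2AX.bedGraph")
write_phospho_tsv(phospho$intensities, phospho$condition, phospho$pair,
                  "scratch/inputs/phospho_matrix.tsv")

summary <- data.frame(
  quantity = c("chromosomes", "genome_bp", "planted_sites", "cut_sites",
               "genic_sites", "genes", "gamma_library", "h2ax_library",
               "proteins", "samples", "missing_fraction"),
  value = c(length(sim$genome), sum(Biostrings::width(sim$genome)),
            nrow(sim$sites), sum(sim$sites$cut), sum(sim$sites$genic),
            nrow(sim$genes), tracks$gamma$library_size,
            tracks$h2ax$library_size, nrow(phospho$intensities),
            ncol(phospho$intensities),
            round(mean(is.na(phospho$intensities)), 4)))
write.table(summary, "results/01_simulation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Simulated ", nrow(sim$sites), " AsiSI sites (",
        sum(sim$sites$cut), " cut) on ", length(sim$genome),
        " chromosomes; gammaH2A.X library ", tracks$gamma$library_size,
        " reads vs H2A.X ", tracks$h2ax$library_size,
        " - the enrichment burden of the damaged chromatin.")
message("Phospho matrix: ", nrow(phospho$intensities), " proteins, ",
        round(100 * mean(is.na(phospho$intensities)), 1), "% missing values.")
message("Inputs written under scratch/inputs/; summary in results/01_simulation_summary.tsv")
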