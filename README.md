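# dsbpipe

Analysis toolkit for sequence-specific DNA double-strand break (DSB)
induction experiments of the AsiSI-ER type, written for genomicists and
proteomicists who need the two bespoke computational procedures such
studies rely on:

1. **Damage-domain calling and cut-site classification.** AsiSI-ER cleaves
   a subset of its genomic GCGATCGC recognition sites after 4OHT induction;
   gammaH2A.X spreads in broad chromatin domains around each break. From
   binned coverage tracks the package computes the depth-normalised
   `log2(gammaH2A.X / H2A.X)` ratio in 10-kb bins, seeds peaks at
   prominent local maxima, extends them until eight consecutive
   non-positive bins, discards calls under 40 kb, scores every recognition
   site by its summed ratio signal in a +/-25-kb window, merges sites
   closer than 10 kb, and labels the top-ranked in-domain sites as
   *efficiently cut* and the lowest-ranked genic non-domain sites as
   *uncut controls*. Reference-point metagene profiles (RPM-normalised
   matrix, 2% trimmed mean, 1-kb rolling mean with SD shadow) and
   +/-500-nt signal-sum condition ratios characterise factor occupancy
   (e.g. Dicer) around the two site classes.

2. **Protein-level phosphoproteomics statistics.** For paired
   control/damage intensity matrices with abundance-dependent missingness:
   log2 + median/MAD normalisation, a two-non-missing filter, two-tier
   left-censored imputation (a one-missing normal rule, then QRILC-style
   truncated-normal draws with quantile-regression parameter estimates),
   per-column re-centring, paired two-tailed t-tests

   `t = mean(d) / (sd(d) / sqrt(n)),  d_k = damage_k - control_k`

   and Storey-type q-values with bootstrap pi0 estimation,

   `pi0(lambda) = #{p > lambda} / (m (1 - lambda)),
    q_(i) = min_{j >= i} pi0 * m * p_(j) / j`.

A seeded synthetic-data module generates every input (FASTA genome with
planted recognition sites, BED site/gene annotations, bedGraph coverage
tracks with plateau-shaped damage domains, base-pair occupancy tracks, TSV
intensity matrices with MNAR missingness), so the whole chain is testable
without external data. The methods vignette
(`vignettes/dsb-damage-and-phospho-methods.Rmd`) documents the model, the
defaults and their rationale.

## Worked example

```r
library(dsbpipe)

cfg <- pipeline_config(seed = 1)          # 4 x 1 Mb genome, 400 sites, 50 cut
res <- run_end_to_end(cfg, "dsb_run")     # writes FASTA/BED/bedGraph/TSV + manifest
```

The same stages can be driven step by step (as the numbered scripts under
`analysis/` do). Running them prints, for seed 1:

```
analysis/01: Simulated 400 AsiSI sites (50 cut) on 4 chromosomes;
             gammaH2A.X library 215719 reads vs H2A.X 39875
analysis/02: 4 damage domains called (median width 1000 kb);
             50/50 planted cut sites fall inside one.
analysis/03: recall 1, precision 1
analysis/04: Rolling-mean occupancy over cut sites peaks at 500 bp from the
             site (planted at +500). Ratio medians: cut 1.4509 vs uncut
             -0.0655 (one-sided Wilcoxon p = 1.297e-30)
analysis/05: With 2 pairs (df = 1) the paired t-test has essentially no
             power at q < 0.05 (0 discoveries); with 4 pairs the same
             pipeline recovers 83% of affected proteins at observed FDR 0.067.
```

Reading the numbers: the gammaH2A.X library exceeds the H2A.X control
because the enriched domain reads are part of its total -- depth
normalisation therefore pushes the ratio background below zero, which is
exactly what the extension rule's "eight non-positive bins" stop criterion
relies on. At this compact simulation density the broad domains of
neighbouring cut sites legitimately merge into chromosome-scale blocks
(hence 4 domains of median width 1 Mb); the +/-25-kb window ranking then
resolves all 50 planted cut sites within the blocks without error. The
occupancy profile recovers the planted +500-nt peak to within one 50-bp
profile bin, and cut sites separate cleanly from uncut ones in the
induced/non-induced ratio. The duplicate paired design has one degree of
freedom per protein and no q < 0.05 power -- a property of the design, not
the pipeline -- while four pairs reach 83% recall at 6.7% observed FDR.

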