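Package: dsbpipe
Title: Damage-Domain Calling, Cut-Site Classification, and Left-Censored
    Phosphoproteomics Statistics for DSB Induction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequence-specific DNA double-strand break
    (DSB) induction experiments of the AsiSI-ER type. Calls broad gammaH2A.X
    damage domains from binned gammaH2A.X/H2A.X log2-ratio ChIP-seq tracks
    (peak seeding, run-length extension, 40-kb length filtering), classifies
    AsiSI recognition sites as efficiently cut or uncut from flanking-window
    signal, builds reference-point metagene profiles with trimmed-mean and
    rolling summaries around site sets, and provides a protein-level
    phosphoproteomics pipeline (median/MAD normalisation, two-tier
    left-censored imputation including a QRILC-style truncated-normal tier,
    paired t-tests, and bootstrap-pi0 q-values). A seeded synthetic-data
    module generates genomes with planted restriction sites, Poisson
    coverage tracks with plateau-shaped damage domains, base-pair-resolution
    occupancy tracks, and left-censored intensity matrices, so every stage
    can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    zoo,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
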