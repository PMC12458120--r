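Package: quantepi
Title: Quantitative Differential Epigenomics Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantitative differential epigenomics:
    peak-level response calling between quantitative (absolute-scale) ChIP
    tracks across biological replicates, mark-specific gain/loss calling with
    a replicate-variance gate, Gaussian-mixture classification of peak widths
    into narrow and broad classes, chromatin-state overlap enrichment with
    18-to-4 state condensation, two-mark proximity linking with k-means signal
    clustering and profile-matrix construction, contiguous-CpG differentially
    methylated region calling from methylation-array beta values, and arrayed
    reporter-screen hit calling by Z-score with expression and viability
    filters. A synthetic-data module generates annotations, tracks, beta
    matrices and screen plates with planted, machine-readable truth so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
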