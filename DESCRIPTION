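Package: chromdyn
Title: Temporal Dynamics of Chromatin Accessibility Across a Developmental Time Course
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for open-chromatin (FAIRE/ATAC-style) time courses
    paired with RNA expression over developmental stages. Provides per-arm
    Z-score filtering of high-fidelity peaks, static/dynamic peak
    classification by pairwise fold change, fraction-of-maximum normalisation
    with k-means temporal clustering and sharp/broad/oscillating cluster
    categories, nearest-TSS peak-to-gene assignment with genomic feature
    classification, accessibility-by-expression quadrant integration and
    trajectory correlations, gene-set accessibility profiles with Mann-Whitney
    tests, position-weight-matrix motif scanning with Fisher enrichment, and a
    seeded synthetic time-course generator with ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
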