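Package: dblkit
Title: Doublet Detection for Single-Cell RNA and ATAC Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects doublets (two cells captured under one barcode) in
    droplet-based single-cell RNA-seq and ATAC-seq data. Artificial doublets
    are simulated from random pairs of real droplets, real and artificial
    droplets are embedded together and summarised through multi-scale
    k-nearest-neighbour features, and a gradient-boosted classifier is trained
    iteratively to score each droplet. Calls combine the classifier
    misclassification trade-off with the expected doublet rate. Also includes
    TF-IDF meta-feature aggregation for sparse accessibility matrices, a
    fragment-overlap (more-than-two-reads) doublet statistic with Fisher
    p-value combination, doublet-origin inference, generalised-linear-model
    tests for cluster stickiness and doublet-type enrichment, synthetic data
    generators with planted doublets, and precision-recall evaluation metrics
    including an adjusted AUPRC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    MASS,
    igraph,
    irlba,
    RANN,
    xgboost,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
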