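Package: scstab
Title: Stability-Based Estimation of the Number of Cell Types in
    Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the number of cell types (k) in a single-cell
    RNA-seq count matrix from the stability of an ensemble of clusterings.
    Each ensemble member clusters a low-dimensional encoding of a random
    gene-subspace projection of the log-normalised data; the agreement
    among members (median pairwise normalised mutual information) is
    scored over a grid of k, and the most stable k is returned together
    with a consensus partition. The package also ships the benchmark
    machinery around the estimator: a negative-binomial simulator of
    labelled cell-type pools, the four-setting subsampling design used to
    build benchmark datasets from a labelled pool, pair-counting
    concordance metrics (adjusted Rand index, normalised mutual
    information, Fowlkes-Mallows, Jaccard), deviation statistics, and a
    good/intermediate/poor performance categorisation rubric.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    mclust,
    optparse,
    scater,
    SingleCellExperiment,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
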