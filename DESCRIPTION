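Package: gpglm
Title: Gamma-Poisson Generalized Linear Models for Single-Cell Count Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Gamma-Poisson (negative binomial) generalized linear models
    gene-by-gene to single-cell RNA-seq count matrices. Per-gene coefficients
    are estimated by deviance-minimizing iteratively reweighted least squares
    with a log link and size-factor offsets; the overdispersion is estimated by
    likelihood maximization over a bundled representation of repeated small
    counts, optionally with a Cox-Reid bias adjustment. Differential expression
    is assessed with a quasi-likelihood F-test using empirical-Bayes shrinkage
    of gene-wise quasi-dispersions, with optional pseudobulk aggregation.
    Counts can be read from MatrixMarket, 10x-style HDF5 or TSV files and
    processed in gene-major chunks so the full matrix never needs to be held
    in memory.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    rhdf5,
    stats,
    utils,
    methods,
    tibble,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
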