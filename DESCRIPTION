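Package: scHiCzero
Title: Structural-Zero Identification and Dropout Imputation for Single-Cell Hi-C
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian hierarchical zero-inflated Poisson modelling of
    single-cell Hi-C contact matrices. Observed zeros are classified into
    structural zeros (locus pairs that truly never interact in a cell) and
    dropouts (sampling zeros due to shallow sequencing), and dropout values
    are imputed by Metropolis-within-Gibbs MCMC with neighborhood-, cell-,
    and bulk-informed priors. Includes a generative simulator with known
    zero labels, three reference smoothers (2D mean filter, 2D Gaussian
    kernel, three-step random walk), evaluation metrics (PTSZ, PTDO,
    correlation and absolute-error summaries, ROC/AUC), and downstream
    clustering utilities (t-SNE, K-means, adjusted Rand index, mega
    matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Rtsne,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
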