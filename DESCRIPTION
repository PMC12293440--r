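Package: cohnet
Title: Wavelet-Coherence Brain Networks for Single-Trial ERP Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts single-trial event-related potential (ERP) epochs into
    wavelet-coherence connectivity graphs per ERP component (N100, N200, P300)
    and frequency band (delta, theta, alpha, beta), extracts surrogate-normalized
    graph-theoretic features (strength, clustering, energy, global efficiency,
    transitivity, characteristic path length), and discriminates two mental
    states with feature selection (t-test, ReliefF, MRMR) and cross-validated
    classifiers (SVM-RBF, LDA, 1-NN). Includes a seeded generator of
    two-condition multichannel epochs with planted band-limited coupling,
    threshold-based artifact rejection, and readers for BrainVision and EDF
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
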