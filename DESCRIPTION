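Package: clamcor
Title: Cluster-Based Association Measures for Heterogeneous Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of nonlinear association between pairs of (possibly
    multivariate) variables -- distance correlation, maximal correlation via
    alternating conditional expectations, the maximal information coefficient,
    Chatterjee's rank correlation, and a checkerboard-copula based coefficient --
    together with data-driven clustering procedures with consistency guarantees
    (neighborhood-graph clustering with denoising, and spectral clustering with
    eigengap selection over density-sensitive path distances). The two are
    combined into cluster-based association measures (CLAM): per-cluster
    association triples and an overall cluster-weighted association value that
    is robust to hidden subpopulations and outliers. Includes seeded simulators
    for Gaussian mixtures, noisy functional relationships, rotated-square
    manifold mixtures and related benchmark designs, and drivers reproducing
    the accompanying simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
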