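Package: dynbmi
Title: Neural Dynamical Filter Decoders with Hysteresis for Brain-Machine Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.com", role = c("aut", "cre"))
Description: Latent linear dynamical system (LDS) decoders for intracortical
    brain-machine interfaces: expectation-maximization systems identification
    with factor-analysis initialization, steady-state Kalman filtering, the
    neural dynamical filter (NDF) and its hysteresis variants (HNDF, MNDF)
    that remember dynamics learned when more electrodes were available,
    plus feedback-intention-trained Kalman filter (FIT-KF) and optimal
    linear estimator (OLE) baselines. Includes mutual-information electrode
    ranking with drop-most-informative-first loss simulation, rotational
    dynamics analyses (eigenspectra, jPCA R-squared ratio, per-eigenmode
    contributions to decoded output), offline decoding metrics, and a
    synthetic center-out-and-back session generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
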