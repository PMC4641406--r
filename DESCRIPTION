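Package: traitbridge
Title: Continuous Trait Evolution on Phylogenies with Ornstein-Uhlenbeck
    Bridge Traitgrams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a battery of models of continuous trait evolution on rooted
    time trees (Brownian motion, accelerating/decelerating rates including
    early bursts, single- and multi-regime Ornstein-Uhlenbeck processes, and
    multi-rate Brownian motion with reversible-jump MCMC shift detection),
    compares them by small-sample-corrected AIC, and visualizes the fitted
    process by forward simulation: trait-range envelopes through time and
    traitgrams whose anagenetic segments follow the Ornstein-Uhlenbeck bridge
    rather than straight lines. Includes Blomberg's K, two-state Markov
    ancestral-state reconstruction for deriving selective-regime paintings,
    covariance-matrix PCA of species means, and seeded synthetic-data
    generators (Yule trees, model simulations) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
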