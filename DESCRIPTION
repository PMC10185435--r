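Package: netdemsim
Title: Simulation of Integrated Social Network and Capture-Recapture Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating integrated ("co-capture") social network and
    capture-recapture datasets with known statistical properties, and for
    testing survival analyses on them. Generates group-structured populations
    in 2-D space, weighted social networks from an adapted stochastic block
    model with spatial distance decay, grouping events (group-by-individual
    matrices) from those networks, survival probabilities driven by individual
    traits and network position (optionally with network-structured
    covariance), and an imperfect capture/observation process. Includes a
    Bayesian Cormack-Jolly-Seber model with a time-varying individual network
    covariate, cross-sectional or longitudinal imputation of missing covariate
    values as latent parameters, highest-density-interval and
    earth-mover's-distance posterior summaries, a k-means convergence screen,
    and workflow drivers for simulation-based power analyses of social effects
    on survival.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    MASS,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
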