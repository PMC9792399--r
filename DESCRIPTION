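Package: fretjump
Title: Photon-by-Photon smFRET Kinetics with Bayesian Nonparametrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the number of conformational states of a biomolecule and
    the full matrix of transition rates from single-photon smFRET traces
    recorded under continuous-wave illumination. The likelihood treats every
    photon arrival individually through matrix exponentials of a composite
    system-photophysics generator, so kinetics are resolved down to
    interphoton timescales without binning. State-number inference uses
    Bernoulli loads on a maximal candidate state space sampled jointly with
    all rates by Metropolis-within-Gibbs. Includes an exact Gillespie
    simulator of photon traces with cross talk, detection loss and Poisson
    background, calibration helpers for route correction matrices, posterior
    summaries, and plotting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
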