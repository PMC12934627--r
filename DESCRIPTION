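Package: ratiosense
Title: Particle-Based Simulation of Ratiometric Gradient Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic simulation and analysis of spatial gradient sensing
    by a spherical cell. Immobile two-state receptors respond to a linear
    ligand gradient while G proteins diffuse on the membrane and update
    their activity on receptor contact, either ratiometrically (copying the
    state of the last receptor met) or classically (activated by bound
    receptors, inactivated at a uniform rate). Includes resultant-vector
    direction estimators with noise-to-signal and angular-error metrics, the
    Fisher-information Cramer-Rao bound for instantaneous receptor
    snapshots, a reduced single-receptor model with an exact
    continuous-time Markov chain oracle, and experiment drivers for
    classical-rate calibration, parameter sweeps and gradient-flip
    adaptation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
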