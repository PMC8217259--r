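Package: mtgamma
Title: Two-Cumulant Mean-Field Analysis of Gamma Oscillations in
    Inhibitory Theta-Neuron Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying interneuron-gamma (ING) oscillations in
    populations of noisy, heterogeneous modified theta (quadratic
    integrate-and-fire) neurons coupled by GABAergic conductances.
    Provides a fast finite-size stochastic network simulator, the
    two-circular-cumulant macroscopic reduction of its Fokker-Planck
    equation together with a Kuramoto-Daido mode-hierarchy reference
    integrator, equilibrium and Hopf-bifurcation analysis for tracing
    stationary/oscillatory regime boundaries in parameter planes, and
    gamma-band (30-200 Hz) spectral power analysis of conductance
    traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
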