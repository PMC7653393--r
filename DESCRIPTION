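Package: blendsim
Title: Blending-Region Hybrid Simulation of Stochastic Reaction-Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation of reaction-diffusion systems across spatial scales:
    a deterministic finite-volume PDE solver (macroscopic), an event-driven
    compartment-based stochastic simulation algorithm (mesoscopic), and
    fixed-time-step Brownian dynamics with lambda-rho bimolecular reactions
    (microscopic). The three engines can be coupled pairwise through a
    blending region in which both representations coexist and share diffusion
    via complementary blending functions, so that control of diffusion passes
    smoothly from one model to the other. Includes analytic reference
    solutions, region-wise relative-mass-error diagnostics, and config-driven
    runners for a set of standard test problems (uniform steady state,
    particle redistribution, morphogen gradient formation, and a
    three-dimensional bimolecular production-degradation system).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
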