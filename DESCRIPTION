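Package: lnakit
Title: Linear Noise Approximation and Noise Optimisation for Biochemical
    Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterises intrinsic molecular noise in single-compartment
    biochemical reaction networks using the linear noise approximation (LNA).
    Detects conserved moieties and reduces the system to independent species,
    locates stable steady states, builds the drift and diffusion matrices, and
    solves the stationary Lyapunov equation with a Schur-based
    Bartels-Stewart solver to obtain particle-number covariances. Covariance
    based noise statistics (variances, covariances, correlation coefficients,
    coefficients of variation, Fano factors) can be scanned over parameter
    grids or optimised globally with particle swarm and evolutionary
    programming algorithms in a closed loop with steady-state and constraint
    checks. An exact Gillespie stochastic simulation oracle validates the
    approximation. Bundled models include the Michaelis-Menten mechanism and
    a MAPK (ERK) signalling cascade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
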