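Package: mbwater
Title: Many-Body Water Potentials, Energy Decomposition and Path-Integral
    Dynamics at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting how low-order many-body interactions shape
    the structure of liquid water, at a scale that runs on a laptop.  Provides
    a polarizable analytic "truth" water potential with swappable short-range
    two-body and three-body terms, controllably distorted surrogate potentials
    emulating density-functional error, an exact many-body expansion of
    cluster energies with stratified (mixed-level) totals, complete-basis-set
    extrapolation and counterpoise arithmetic, permutation-invariant
    polynomial fitting of short-range terms, normal-mode path-integral
    molecular dynamics in the NVE, NVT and NPT ensembles with Nose-Hoover
    chain thermostats and Ewald electrostatics, and structural diagnostics
    (radial distribution functions, tetrahedral order parameter) with
    bead averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
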