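Package: anthowalk
Title: Kinetic Modelling and Adaptive-Walk Simulation of the Anthocyanin Pathway
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A kinetic model of the core anthocyanin biosynthesis pathway
    (irreversible generalized Michaelis-Menten rate laws with substrate
    competition, fixed precursor influx and a shared first-order sink) together
    with an origin-fixation evolutionary simulator for flower-colour
    transitions. Mutations are multiplicative gamma-distributed shifts to
    single kinetic or enzyme-concentration parameters; fitness is a Gaussian
    function of the target-pigment ratio; beneficial mutations fix with
    probability 1 - exp(-s). Includes metabolic control analysis
    (concentration control coefficients by log-central finite differences),
    trajectory-ensemble summary statistics (hotspot shares, mutation-type
    splits, directional shifts, per-step selection-coefficient distributions,
    fixation-order heatmaps, pigment-space trajectories), and a command-line
    interface for reproducible simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    deSolve,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
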