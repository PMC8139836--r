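Package: cdtaxis
Title: Corollary-Discharge Feedback Model of C. elegans Thermotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reduced dynamical-systems model of the C. elegans thermotaxis
    circuit in which corollary-discharge feedback from the motor command onto
    a first-layer interneuron sustains forward-run activity states, together
    with an agent-based simulator of biased-random-walk navigation on a
    linear thermal gradient, analysis pipelines for ratiometric calcium
    traces (delta-R/R0, Otsu binarization, Gaussian-mixture activation-state
    segmentation, event-triggered averages, state-conditioned
    cross-correlograms) and for behavioral trajectories (thermotactic bias,
    run segmentation, cooling-epoch statistics), the accompanying statistical
    toolkit (Wilcoxon tests, Benjamini-Hochberg adjustment, bootstrap
    confidence intervals), and seeded synthetic-data generators with ground
    truth for end-to-end recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
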