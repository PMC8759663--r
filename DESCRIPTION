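Package: spotdyn
Title: Agent-Based Simulation and Quantitative Analysis of Motile Bacterial Aggregates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the formation, collective motion, and merging of
    macroscopic bacterial aggregates. Implements a two-dimensional agent-based
    chemotaxis model in which Brownian agents secrete a diffusing, decaying
    chemoattractant, drift up its gradient under receptor-law sensitivity, and
    undergo a transient density-dependent motility transition (threshold-triggered
    immobilization, a fixed refractory interval, stochastic reactivation, and a
    gradient-blind interval). Provides the companion quantification pipeline:
    density-based aggregate segmentation and track linking with merge-event
    classification, spatial point-pattern statistics (Voronoi neighbor distances,
    radial pair correlation, structure factor, random and hard-sphere null
    patterns), and trajectory kinematics (speeds, path directness, anomalous
    diffusion exponents, constant-acceleration merging fits, and force-law fits),
    together with synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
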