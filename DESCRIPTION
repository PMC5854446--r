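Package: chemosense
Title: Temporal Versus Spatial Gradient Sensing in Chemotactic Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates three-node adaptive signaling circuits (negative
    integral feedback and incoherent feedforward) on a one-dimensional ring
    cell moving through a chemoattractant gradient, in fully dimensionless
    form. Provides log-uniform parameter screening for sensitivity and
    adaptation precision, method-of-lines reaction-diffusion integration on
    the ring, temporal and spatial sensing output functionals with a strategy
    decision rule, factorial sweeps over the dimensionless groups (beta,
    D'_A, D'_B, alpha), stochastic ensembles under external chemoattractant
    noise and internal kinetic-parameter noise with viability criteria, and a
    cell-atlas classifier that places real cells (speed, diameter, signaling
    rate) relative to the temporal/spatial decision boundary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
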