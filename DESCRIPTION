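Package: ppsimpact
Title: Normative Bayesian Impact Prediction and Peripersonal Space
    Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a Bayesian ideal observer that predicts whether a
    moving object will contact the body within a short time horizon, given
    noisy percepts of its position and velocity and an asymmetric
    false-positive/false-negative loss.  The optimal graded contact
    prediction, obtained by minimising expected loss, delineates a
    peripersonal space (PPS) around the body.  The package provides the
    one-dimensional model in closed form, a three-dimensional extension
    with a rectangular body-part collision plane and Monte-Carlo hit
    probabilities, distance-sweep simulation experiments with presets,
    PPS-boundary metrics (detection-threshold rule, fitted sigmoid
    midpoint, boundary slope), and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
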