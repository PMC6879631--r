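Package: digitrack
Title: Attention-Map Analysis for Digit-Tracking and Eye-Tracking Exploration Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring and analysing visual attention from
    gaze-contingent exploration records.  Supports foveated-display geometry
    (pixel/degree conversion, Gaussian blur plus aperture compositing, a
    path-length stopping rule), duration-weighted kernel-density attention
    maps with unity normalisation, reliability statistics (inter-subject
    correlation, convergence-to-stability, split-half stability), a linear
    feature-readout saliency model with correlation-based and
    lasso-regularised learners, and per-subject clinical deviation scores
    (exploration neurotypicality, laterality) with density-fitted ROC/AUC
    discrimination.  A synthetic-data module simulates saliency-driven eye
    fixations, finger trajectories and population-level effects so the full
    pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
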