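Package: fundysdm
Title: Presence-Only Maximum-Entropy Habitat Models for Basking Sharks in the Bay of Fundy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for presence-only species distribution
    modelling of basking sharks (Cetorhinus maximus) in the lower Bay of
    Fundy and northeastern Gulf of Maine. Provides an ESRI ASCII raster
    data model with terrain derivatives and isobath-distance layers,
    spatial thinning of sightings by the average nearest neighbor
    statistic, a from-scratch L1-regularized maximum-entropy density
    estimator with linear, quadratic, product, threshold and hinge
    features, AICc-based regularization selection, cross-validation,
    bootstrap and subsampling model-fitting routines with ROC/AUC
    evaluation, variable-importance metrics, threshold-based habitat
    delineation, month-to-month comparison of suitability surfaces via
    the Brownian distance correlation coefficient, and a seeded
    synthetic-data generator emulating the study system for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
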