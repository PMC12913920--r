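Package: microgrid
Title: Forest Microclimate Grids from Logger Networks, Terrain and Canopy Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mapping forest understorey microclimate
    at very high spatial resolution. Calibrates and summarises 15-minute
    temperature logger series into annual microclimate variables (mean,
    percentile extremes, growing degree days at three measurement heights),
    derives land-surface and forest-structure predictors from terrain and
    canopy rasters (slope, aspect, topographic position and wetness indices,
    SAGA wetness index via Freeman multiple-flow routing, diurnal anisotropic
    heating, canopy density and height), selects and fits componentwise
    gradient-boosted spatial generalized additive models with P-spline base
    learners, evaluates them by hexagonal spatial block cross-validation, and
    applies them over predictor stacks to produce microclimate grids with an
    extrapolation-uncertainty raster. A seeded synthetic-world generator with
    known ground truth supports recovery testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
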