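Package: dfrfa
Title: Coupled Dynamic Factor and Random Forest Analysis of Vegetation Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models polygon-scale NDVI from monthly environmental covariate
    series with a dynamic factor (state-space) model fitted by EM with a
    Kalman smoother, detects pixels where the model under- or over-predicts
    with the seasonal Mann-Kendall test and Sen's slope, and attributes the
    resulting residual-trend surfaces to discrete social and physical
    covariates with a random-forest classifier and out-of-bag importance
    analysis. Includes a seeded synthetic-landscape generator emulating a
    semi-arid savanna with a north-south precipitation gradient, plain-text
    raster (ESRI ASCII grid) and GeoJSON vector I/O, and terrain, distance,
    buffer and zonal-statistics derivations.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
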