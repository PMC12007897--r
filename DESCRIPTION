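Package: airlur
Title: Land-Use Regression Exposure Modelling with Partial Least Squares
    and Universal Kriging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A national-scale land-use-regression (LUR) workflow for ambient
    criteria air pollutants: completeness-based quality control of regulatory
    monitor time series (including the May-September ozone daily maximum 8-h
    metric), buffer-based extraction of geographic predictor variables,
    dimension reduction by partial least squares feeding a universal-kriging
    mean model with exponential spatial covariance fit by maximum likelihood,
    forward variable selection by partial F-statistic, conventional and
    spatially clustered 10-fold cross-validation, prediction at census-block
    centroids and population-weighted aggregation to block group, tract and
    county. Includes a synthetic spatial data generator with a known ground
    truth so every pipeline stage can be tested against recoverable
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
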