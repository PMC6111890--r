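Package: forestmgmt
Title: Forest Management Mapping from Vegetation-Index Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to map forest management regimes (production, ecological,
    passive and preservation forestry) from satellite vegetation-index time
    series. Implements quality-assurance masking and gap interpolation of
    16-day EVI series, a season/trend/break decomposition with
    dynamic-programming least-squares segmentation, the 29 break-summary
    variables plus spectral entropy used as classifier covariates, ancillary
    covariate construction (road density, ownership crosswalk, fine-class
    proportion upscaling), a weighted random-forest classification protocol
    with covariate pruning, confusion-matrix accuracy assessment with
    stratified cross-validation, and a Bayesian Monte-Carlo analysis of
    aggregation uncertainty for categorical maps. A synthetic-landscape
    generator with known ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
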