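Package: nasoform
Title: Nasal-Bone Morphometry from Calibrated 2D Photogrammetry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional nasal photogrammetry: a canonical
    catalog of 29 facial anthropometric landmarks over frontal, lateral and
    basilar views; ruler-based pixel-to-millimetre calibration; linear,
    angular and symmetry-ratio measurements; a from-scratch convolutional
    network for landmark localization with reference forward/backward
    implementations; rule-based nasal-bone shape classification (lateral V/S,
    frontal types A-E) and a back-propagation network predicting bone
    dimensions and shape classes from surface measurements and body
    covariates; evaluation metrics (MAE, R-squared, mean average precision)
    and group statistics; and a synthetic-data generator producing
    morphometric populations and rendered three-view images with ground-truth
    landmarks and a calibration ruler.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
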