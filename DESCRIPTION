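Package: conformalfd
Title: Joint Elastic Registration and Conformal Prediction for Partially
    Observed Functional Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distribution-free pointwise prediction bands for functional data
    observed only on part of their domain. Implements full functional conformal
    prediction (FFCP), split functional conformal prediction with elastic
    registration of the calibration set to a training Karcher mean (SFCP), and
    split conformal prediction of the relative phase under a monotonicity
    constraint (SFCPP). Includes the square-root slope function (SRSF)
    machinery these methods rely on: dynamic-programming pairwise alignment
    under the Fisher-Rao metric, Karcher means of aligned functions, amplitude
    and warping distances, neighborhood-smoothing prediction with bandwidth
    selection, generators for two-peak simulation populations with Beta-CDF
    phase variation, and a Monte Carlo harness for coverage and interval-length
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
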