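Package: noisetissue
Title: Intrinsic and Extrinsic Gene-Expression Noise in Plant Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stochastic gene expression in intact
    tissues from nucleus-level fluorescence measurements. Implements an
    exact stochastic simulator of the two-stage expression model with a
    photoconvertible (green-to-red) reporter and cell-to-cell variation
    in translation rate, closed-form moment and autocorrelation oracles,
    dual-reporter decomposition of expression noise into intrinsic and
    extrinsic components, a covariance-normalized estimator of the
    spatial coupling of extrinsic noise between neighbouring cells with
    a randomization test and distance-tier profiles, a cell-division
    inheritance simulation, and a synthetic-tissue generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
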