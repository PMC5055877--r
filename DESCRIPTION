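Package: fermrsm
Title: Response Surface Optimization and Unstructured Kinetics for Batch Fermentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for statistical optimization of microbial fermentation
    conditions and for unstructured kinetic modelling of batch cultures.
    Builds face-centered central composite designs over coded factors, fits
    second-order (quadratic) response-surface models with sequential model
    comparison, ANOVA with lack-of-fit partitioning, and prediction
    diagnostics (PRESS, predicted R-squared, CV%, RMSE, AAD%), and locates
    constrained optima on the coded cube. Simulates and estimates logistic
    biomass growth together with Luedeking-Piret product-formation and
    modified Luedeking-Piret substrate-consumption kinetics, with bounded
    nonlinear least-squares parameter estimation. Includes a seeded
    synthetic-data generator for design/response tables and fermentation
    time-courses, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
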