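Package: slimlm
Title: Minimalist Variable Selection for High-Dimensional Linear Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds small linear prediction models from datasets with far
    more predictors than samples (n << p), such as genome-wide DNA
    methylation arrays. Predictors are screened by marginal Pearson
    correlation with the outcome, queued in descending absolute
    correlation, and admitted to the model by greedy forward selection
    with a residual-correlation shortcut and an adjusted-R-squared
    improvement gate, fitted by QR-decomposition least squares. Includes
    calibration regression of observed on predicted outcomes, a paired
    bootstrap F-test comparing residual variances of two predictors,
    greedy reduction of a fitted model on test data, and synthetic-data
    generators (pure-noise and planted sparse signals with correlated
    blocks) for false-positive and parameter-recovery studies. A
    command-line interface exposes training, prediction, comparison and
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    optparse,
    parallel,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
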