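Package: cdtransfer
Title: Threshold Regression Analysis of Cadmium Transfer from Soil to Wheat
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-regime threshold regression for soil-plant trace-metal
    transfer studies: concentrated least-squares threshold estimation over a
    trimmed grid of observed values, likelihood-ratio sequences with
    inversion-based confidence sets for the threshold, and a residual
    bootstrap sup-F test for the existence of a threshold effect. Also
    provides the surrounding study computations (bioconcentration factors,
    Tessier speciation percentages, summary statistics with coefficients of
    variation, Pearson correlation tables, regulatory exceedance screening),
    a synthetic data generator emulating a 22-sample soil-wheat survey, and a
    reproducible pipeline that runs the full analysis from a seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
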