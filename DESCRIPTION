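Package: roughpnn
Title: Decision-Theoretic Rough-Set Attribute Reduction and Probabilistic
    Neural Network Classification for Clinical Tabular Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-parameter decision-theoretic rough-set (SPDTRS) attribute
    reduction over real-valued two-class decision tables, driven by neighborhood
    granulation and a loss-function matrix generated from a lone compensation
    coefficient, combined with a probabilistic neural network (Parzen-kernel)
    classifier. Includes a native reader for the Wisconsin Diagnostic Breast
    Cancer file dialect, min-max scaling, seeded stratified splitting, confusion
    metrics with Wilson score intervals, parameter-sweep experiments for the
    compensation coefficient and kernel spread, a seeded generator of WBCD-like
    synthetic tables, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
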