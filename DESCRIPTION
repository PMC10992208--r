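Package: stovernet
Title: Neural-Network Prediction of Glucose and Phenolics in Corn Stover
    Hydrolysate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the combined dilute inorganic acid pretreatment and
    enzymatic hydrolysis of corn stover with a single-hidden-layer
    feedforward neural network (6-n-2 topology) that jointly predicts
    glucose concentration and total phenolic content in the hydrolysate
    from six operating variables. Provides min-max normalisation to
    [-1, 1] with exact inverse, Adam mini-batch training, an RMSE-driven
    hidden-layer architecture search, parity evaluation of predictions
    against measurements, and Garson connection-weight partitioning for
    per-input relative importance. A seeded synthetic-data generator
    emulates the pretreatment response surface so the whole pipeline is
    testable without the original experimental table.
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
    lhs,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
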