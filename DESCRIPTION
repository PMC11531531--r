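Package: fuzzyhisto
Title: Fuzzy Deep Classification of Histopathology Tiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for binary classification of histopathology
    tile images (cancer versus non-cancer): geometric image augmentation,
    deep-feature extraction behind a pluggable backbone interface,
    decision-tree recursive feature elimination, Wang-Mendel fuzzy rule
    induction with configurable membership functions, a trainable
    neuro-fuzzy classifier with fuzzification and defuzzification layers,
    and a confusion-matrix metric suite. Seeded synthetic image and feature
    generators make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    pracma,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
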