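Package: lineupmpt
Title: Two-High-Threshold Multinomial Model for Eyewitness Lineup Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the two-high-threshold (2-HT) multinomial processing tree
    model of eyewitness identification decisions to per-condition response
    frequencies from lineup experiments. Separates culprit-presence detection,
    culprit-absence detection, biased suspect selection and guessing-based
    selection, with the random-sampling probability entering as a fixed
    constant equal to one over the lineup size. Provides constrained
    maximum-likelihood estimation across multiple lineup conditions with
    equality and fixed-value parameter restrictions, likelihood-ratio
    goodness-of-fit and nested-model tests, noncentral chi-square
    sensitivity and power calculations, a model-based data simulator with a
    parameter-recovery harness, and packaged response-frequency tables from
    a published two-experiment study of lineup-size effects.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
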