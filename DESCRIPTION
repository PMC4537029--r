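Package: dlsynergy
Title: Difference-in-Logarithms Synergy Analysis for Photodynamic
    Therapy Combination Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for preclinical drug-combination
    studies of photodynamic therapy (PDT) with EGFR inhibitors. Converts
    plate-reader signals to background-corrected survival fractions, scores
    combination treatments with the difference-in-logarithms (DL) statistic
    under Bliss independence and classifies them as synergistic, additive or
    antagonistic via a two-sided t-test; summarises xenograft tumor growth,
    applies an in-vivo DL analog to relative tumor burden, and estimates
    Kaplan-Meier survival under ethical-limit censoring; includes serum
    toxicity-panel calculators (creatinine, urea nitrogen, AST/ALT kinetic
    activity) and a synthetic-data generator with known ground truth so every
    stage is testable without raw study data.
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
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
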