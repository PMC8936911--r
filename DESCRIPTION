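Package: f1ci
Title: Confidence Intervals for Micro- and Macro-Averaged F1 Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point estimation, multivariate delta-method variance estimation,
    and Wald confidence intervals for the micro-averaged F1 score and two
    macro-averaged F1 scores (the arithmetic mean of per-class F1, and the
    harmonic mean of macro precision and macro recall) of a multi-class
    classifier, treating the confusion matrix as a single multinomial sample.
    Includes per-class precision/recall/F1 summaries, a numerical
    delta-method engine used to certify the closed-form variances, a
    multinomial simulation engine for coverage-probability studies, report
    serialization, and a small command-line interface.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
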