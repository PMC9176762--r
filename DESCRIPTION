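Package: gcsrasch
Title: Psychometric Evaluation of the Glasgow Coma Scale by Rasch Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating whether the three Glasgow Coma Scale
    sub-scales (Eye, Verbal, Motor) support a summed total score, using the
    polytomous Rasch partial credit model. Provides a conditional
    maximum-likelihood estimation engine built on elementary symmetric
    functions, RUMM-style diagnostics (fit residuals, item-trait interaction
    chi-square, person separation index, Cronbach's alpha, Andrich threshold
    ordering and category probability curves), a category-collapse rescoring
    engine with candidate enumeration, cross-validated logistic and
    random-forest mortality models compared by strictly proper scoring rules,
    and a synthetic trauma-registry generator calibrated to published cohort
    constants for reproducible end-to-end experiments.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
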