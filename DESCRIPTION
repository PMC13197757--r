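Package: yeastME
Title: Metabolizable Energy Determination and Prediction for Sugarcane
    Yeast in Broiler Diets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for total-excreta-collection metabolism
    trials in broiler chickens. Computes nitrogen balance, apparent
    metabolizable energy (AME), nitrogen-corrected AME (AMEn) and
    metabolizability coefficients per experimental unit and per diet,
    extracts ingredient-level energy by the substitution method (70%
    reference diet + 30% test ingredient), fits and selects
    composition-based prediction equations by stepwise backward
    elimination on AIC, and validates equations against in vivo values
    by sum of squared deviations. Ships the physicochemical composition,
    trial summaries and published prediction-equation registry for four
    sugarcane yeast samples as plain-text fixtures, plus a synthetic
    trial generator with known ground truth for end-to-end testing and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
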