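Package: eyescreen
Title: Community Eye-Screening Referral Algorithms and Diagnostic Accuracy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Encodes a smartphone-guided referral algorithm for community eye
    screening, developed over seven iterations, together with the
    diagnostic-accuracy machinery used to validate it against an ophthalmic
    clinical officer reference standard: Snellen/logMAR visual-acuity handling
    with referral thresholds, the seven-iteration rule catalog producing
    refer/do-not-refer decisions with reason codes, exact (Clopper-Pearson)
    confidence intervals for sensitivity, specificity and predictive values,
    Cohen's kappa with 2x2 reconstruction from printed marginals, Buderer
    sample-size calculations, logistic-regression association checks, and a
    calibrated synthetic screening-population simulator so the whole pipeline
    is exercisable without study data.
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
    stringr,
    tibble,
    tools,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
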