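Package: snbrecal
Title: Clinical-Utility-Targeted Recalibration of Risk Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recalibrating a clinical risk model when the model is
    used to recommend an intervention above a mandated risk threshold.
    Clinical utility is measured by standardized net benefit (sNB). The
    package provides a graphical assessment of the potential gain in sNB
    achievable by recalibration, standard (Cox) logistic recalibration,
    weighted logistic recalibration that prioritizes calibration at or near
    the risk threshold, and constrained logistic recalibration that maximizes
    the logistic likelihood subject to near-maximal sNB. Cross-validated
    tuning of the weight function, bootstrap optimism correction of sNB, and
    a simulator for miscalibrated risk scores (Beta-mixture true risks with
    monotone piecewise-polynomial miscalibration) are included.
License: MIT
Encoding: UTF-8
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
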