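Package: samecost
Title: Smoking-Attributable Medical Expenditures from Longitudinal Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the smoking-attributable fraction (SAF) and
    smoking-attributable medical expenditures (SAME) from person-wave panel
    survey data with a two-part econometric model: a random-effects logit for
    any use of a health-care service and a random-effects GLS regression on
    log expenditure among users, combined into factual and counterfactual
    (never-smoker) expected costs and scaled to national totals with a
    survey-to-official calibration factor. Includes a synthetic balanced-panel
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
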