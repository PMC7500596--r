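Package: survenrich
Title: Prognostic Enrichment of Time-to-Event Clinical Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates biomarkers for prognostic enrichment of clinical trials
    with censored time-to-event endpoints. Across a grid of biomarker screening
    thresholds, estimates the expected event rate in the enriched subpopulation
    (Kaplan-Meier or nearest-neighbor survival estimation), the trial sample
    size implied by a log-rank test of a target treatment hazard ratio, the
    number of patients that must be screened to enroll the trial, and total
    trial cost, with delta-method and bootstrap standard errors. Supports
    fixed-duration designs and designs with a uniform accrual period followed
    by a follow-up period (Simpson's-rule event rates). Includes a Weibull
    proportional-hazards data simulator so the analysis can be explored for a
    planned clinical setting without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
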