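Package: adherits
Title: Medication Adherence Scoring and Interrupted Time Series Analysis
    of Pharmacy Dispensation Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scores long-term medication adherence from prescription
    dispensation claims using the proportion of days covered (PDC) with
    sequential supply stacking and death censoring, aggregates patient-level
    results to group-month time series, and estimates immediate, gradual,
    and counterfactual overall intervention effects by segmented linear
    regression with first-order autoregressive errors fit by restricted
    maximum likelihood.  Includes a synthetic claims generator with
    known-truth intervention effects so that every stage of the pipeline can
    be exercised and validated without access to restricted registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
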