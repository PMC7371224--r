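Package: chartrisk
Title: Chart-Based Cardiovascular Risk Stratification and Treatment Cost
    Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying survey cohorts by 10-year cardiovascular
    disease risk with non-laboratory risk charts (age, sex, smoking, systolic
    blood pressure and body-mass index), classifying treatment eligibility
    under a total-risk versus a single-risk-factor (hypertension) strategy,
    and projecting annual generic drug costs per million adults aged 40 and
    over. Includes a synthetic cohort and chart-fixture generator calibrated
    to a national Bangladeshi survey scenario, proportion confidence
    intervals, chi-square sex comparisons, and CSV input/output for charts,
    cohorts, drug prices and population strata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
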