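Package: afvalidate
Title: External Validation of Multi-Outcome Risk Equations in Atrial
    Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating coefficient-driven Cox risk
    equations (such as the GARFIELD-AF 2017 and 2021 tools) and the
    CHA2DS2-VASc and HAS-BLED point scores on incident atrial-fibrillation
    cohorts. Implements horizon-specific discrimination (AUC/C-statistic
    under censoring with DeLong confidence intervals and paired
    comparisons), Kaplan-Meier observed risk, calibration-in-the-large and
    quantile calibration, missingness accounting, complete-case and
    subgroup analyses, and adjusted treatment-effect estimation, together
    with a synthetic incident-AF cohort simulator with known ground truth
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
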