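Package: nephroref
Title: Risk-Based Nephrology Referral Modelling with the Kidney Failure
    Risk Equation under Competing Risks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compute and locally recalibrate the four-variable
    Kidney Failure Risk Equation (KFRE) on longitudinal laboratory data,
    encode rule-based nephrology referral criteria (KDIGO 2012 and
    configurable threshold rules), and compare risk-based against
    rule-based referral with a full competing-risk evaluation:
    Aalen-Johansen cumulative incidence, decile calibration,
    cumulative/dynamic ROC with Youden threshold selection, truncated
    C-index, IPCW Brier score, net reclassification improvement and
    decision curve analysis, all treating death as a competing event.
    Includes a seed-reproducible synthetic cohort generator emulating a
    regional healthcare-utilisation registry (repeated creatinine and
    albuminuria tests, pharmacy dispensations, cause-specific kidney
    replacement therapy and death hazards) and an end-to-end pipeline
    with tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
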