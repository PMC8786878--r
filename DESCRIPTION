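Package: fairicu
Title: Fairness and Generalizability Audits for ICU Mortality Risk Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A three-stage fairness-and-generalizability audit for binary
    clinical risk-prediction models, built around in-hospital mortality
    prediction for ICU stays. Provides a synthetic ICU cohort generator that
    emulates the demographic structure, group-specific outcome rates and
    physiological-variable missingness of real critical-care cohorts;
    descriptive cohort screening (demographics, outcome and missingness
    tables with benchmark exclusion rules); discrimination metrics (AUROC,
    AUPRC, threshold metrics) with bootstrap confidence intervals;
    calibration assessment with exponential-quantile risk groups, Wilson
    score intervals and LOWESS smoothing; and fairness assessments
    (classification parity with class-imbalance-aware interpretation,
    per-group calibration-in-the-large, and Charlson comorbidity versus risk
    percentile curves), orchestrated across internal validation, external
    validation and retrained internal validation stages.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
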