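Package: womacpr
Title: Derivation and Internal Validation of WOMAC-Based Clinical
    Prediction Rules for Poor Outcome After Knee Arthroplasty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving and internally validating clinical
    prediction rules that flag patients at risk of a poor
    patient-reported outcome six months after total knee arthroplasty.
    Scores the 24-item WOMAC osteoarthritis index to standardized 0-100
    subscale and total scores with guideline-style missing-item
    imputation, defines poor outcome as the worst quintile of six-month
    total scores, grows Gini-criterion classification trees over ordinal
    items with a bespoke recursive-partitioning engine, flattens trees
    into sequential question-based rules and selects among candidates by
    a sensitivity-first policy, computes the full diagnostic-validity
    panel (sensitivity, specificity, predictive values, likelihood
    ratios, AUC) with Wilson, Simel log-method and Hanley-McNeil
    confidence intervals, and validates a fixed rule by seeded bootstrap
    resampling. A seeded synthetic-cohort generator with a planted
    answer-pattern rule makes the whole pipeline testable end to end
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    rpart,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
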