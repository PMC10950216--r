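Package: akireason
Title: Individual Predictive Reasoning Analysis of Acute Kidney Injury
    During Immune Checkpoint Inhibitor Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and stages creatinine-defined acute kidney injury
    (AKI) episodes under KDIGO criteria in immune-checkpoint-inhibitor
    treated cancer patients, trains a gradient-boosted decision-tree
    model that continuously predicts AKI within 7 days from sliding
    4-week windows of electronic-medical-record features, computes exact
    per-timepoint Shapley-value attributions, clusters patients by their
    predictive-reasoning signature immediately before first AKI, and
    validates clusters against mechanism labels and 90-day Kaplan-Meier
    survival. Includes a synthetic EMR cohort generator with planted AKI
    mechanisms for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    xgboost,
    survival,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
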