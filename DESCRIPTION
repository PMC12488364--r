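Package: netarm
Title: Association Rule Mining of Clinical and Biomarker Data for
    Neuroendocrine Tumor Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for discovering combinations of plasma
    protein biomarkers and clinical characteristics associated with
    3-year disease progression in grade 1-2 neuroendocrine tumors.
    Provides a synthetic patient/control cohort generator with plantable
    ground-truth rules, control-cohort confidence-interval discretization
    of continuous biomarkers into categorical items, a from-scratch
    level-wise Apriori miner with support/confidence/lift, rule
    filtering, redundancy removal and ranking, composite-consequent
    subgroup characterization, rule-as-classifier diagnostics
    (PPV/NPV/sensitivity/specificity), and supporting group statistics
    (z-based confidence intervals, least-squares-means ANOVA with a
    treatment covariate, logistic likelihood-ratio tests, rank-based ROC
    AUC).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
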