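Package: gwaskd
Title: Cross-Cohort Knowledge Distillation for SNP-Based Disease Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transferring genome-wide association study (GWAS) risk
    models across cohorts. Provides a multi-cohort synthetic genotype
    simulator with planted causal and epistatic variants, cross-cohort SNP
    feature selection (trend-test association scan, ANOVA F-score, mutual
    information, top-rank intersection), a Wide-Deep neural teacher with
    multi-head attention over SNP tokens, temperature-based knowledge
    distillation into a lightweight student, teacher-feature extraction for
    tree-ensemble classifiers, four source-to-target transfer scenarios with
    leakage-audited evaluation, and a sampling Shapley-value attribution of
    student predictions per cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
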