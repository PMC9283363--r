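Package: t1dglyco
Title: Plasma and IgG N-Glycome Analysis at Type 1 Diabetes Onset
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for analysing HILIC-UPLC N-glycan
    chromatogram peaks from plasma and IgG in sibling-pair cohorts at the
    onset of type 1 diabetes. Provides total-area normalisation, empirical
    Bayes batch correction, rank-based inverse normal transformation,
    derived glycosylation trait computation, per-glycan association models
    (sex by age group, censored autoantibody levels, autoantibody counts,
    family-clustered disease status), and a glycan-based discriminative
    model using elastic-net penalised mixed-effects logistic regression with
    family-grouped cross-validation and paired bootstrap AUC comparison.
    Includes a synthetic sibling-pair cohort generator for testing every
    stage without registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    sandwich,
    stats,
    sva,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
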