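Package: pedvisit
Title: Masked Diagnosis Modeling and Next-Visit Prediction for Pediatric
    Visit Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling longitudinal pediatric inpatient and
    emergency-department visit histories coded at the ICD-9 two-digit
    sub-chapter level. Provides a seeded generator of linked mother-baby
    claims records, cohort filtering and leakage-safe patient splits, visit
    tokenization with masked-language-model corruption, a from-scratch
    transformer encoder (bidirectional or causal) pre-trained on masked
    diagnosis prediction and fine-tuned to predict the principal diagnosis
    and length-of-stay class of a patient's next visit, multi-hot logistic
    regression and balanced random-forest comparators, ranking metrics
    (average precision, ROC AUC) with per-patient and per-class averaging,
    embedding diagnostics (cosine similarity, t-SNE maps, an extrinsic
    gender association test), and subgroup fairness reports.
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
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
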