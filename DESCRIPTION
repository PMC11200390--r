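Package: radshap
Title: Explainable Ordinal Classification of Radiomic Feature Tables with
    Shapley-Scaled Principal Component Loadings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for BI-RADS-style four-class classification of slice-wise
    radiomic feature tables and for explaining the resulting predictions at
    the level of individual radiomic features. Provides patient-stratified
    train/validation/test splitting with per-class representation constraints,
    training-set standardization followed by principal component analysis, a
    compact feed-forward classifier with class-weighted cross-entropy loss,
    Shapley value attribution of class probabilities to principal components
    (exact coalition enumeration and Kernel SHAP), and back-projection of
    those attributions onto radiomic features via Shapley-scaled loading
    vectors with feature-type aggregation and percentile filtering, at both
    the single-slice and the class level. Includes a synthetic feature-table
    generator emulating an ordinal latent enhancement gradient with
    within-patient correlation and class imbalance, and bootstrap evaluation
    (accuracy, Cohen's kappa, adjacent-class misclassification).
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    arrow,
    e1071,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
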