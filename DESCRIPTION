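Package: awca
Title: Robust PAM50 Intrinsic Subtyping with AWCA References and
    Regularized Multiclass Logistic Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nearest-centroid intrinsic subtyping of breast cancer
    RNA-seq profiles (the PAM50 scheme) with robust reference-profile
    construction. The standard workflow centres log2 expression against
    a median reference built from an estrogen-receptor-stratified sample
    subset; this package additionally implements the AWCA reference
    (average of within-class averages), which is invariant to subtype
    class sizes and enables stable single-sample classification against
    a fixed external reference. Also provides risk-of-recurrence (ROR)
    scoring as a configurable weighted sum of centroid correlations,
    an elastic-net-regularized multiclass logistic-regression subtype
    caller with stratified cross-validation and hyperparameter grid
    search, filter/DEG/backward-elimination feature selection, a
    concordance and Cohen's kappa evaluation harness, and a synthetic
    cohort simulator with planted subtypes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    limma
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'evaluation.R'
    'feature-selection.R'
    'io.R'
    'mlr.R'
    'pam50.R'
    'reference.R'
    'ror.R'
    'simulate.R'
    'utils.R'
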