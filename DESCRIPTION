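Package: deltaradiomics
Title: Longitudinal DCE-MRI Delta-Radiomics for Early Prediction of
    Pathologic Complete Response
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for longitudinal dynamic contrast-enhanced
    MRI radiomic analysis of treatment response in triple-negative breast
    cancer. Constructs tumoral and 10 mm peritumoral regions of interest,
    extracts a 310-feature set (10 first-order histogram statistics plus
    300 rotation-invariant gray-level co-occurrence matrix features over
    five gray-level quantizations), forms absolute and relative delta
    features across three treatment time points, screens features by
    dual-cohort AUC, fits elastic-net-regularized logistic regression
    models tuned by cross-validated AUC, and quantifies interreader
    reliability. Includes a synthetic longitudinal cohort generator and
    minimal NIfTI-1 input/output so the entire pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
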