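Package: stavarsel
Title: Stable Biomarker Selection with Conservative Cross-Validation Error Bounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stabilized three-stage nested cross-validation (StaVarSel) for
    selecting expression-ratio biomarkers with penalized logistic regression,
    together with a conservative Monte-Carlo n-2 subsampling (general
    jackknife) estimator of the variance of cross-validation prediction
    errors. Includes quality control for circulating miRNA profiles
    (low-expression filtering, global outlier detection, molecular haemolysis
    detection), all-pairs expression-ratio feature construction with
    per-training-set prefilters, standard two-stage nested cross-validation
    with Lasso and relaxed-Lasso refits, per-sample nonparametric confidence
    intervals for held-out prediction probabilities, worst-case specificity
    and sensitivity bounds, and a seeded synthetic cohort generator so the
    whole pipeline runs without external data.
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
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
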