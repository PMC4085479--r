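Package: kinestroke
Title: Lognormal Kinematic Modelling of Pen Movements for Stroke
    Risk-Factor Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for synthesising and analysing rapid pen movements under
    the lognormal family of neuromotor models (delta-, sigma- and
    omega-lognormal), extracting model parameters from sampled pen
    trajectories, aggregating robust per-subject kinematic features
    (median and median absolute deviation), and classifying the presence
    of cerebrovascular risk factors with leave-one-subject-out
    cross-validated logistic regression and linear discriminant analysis,
    reported as ROC/AUC matrices.  Includes a synthetic cohort generator
    emulating a nine-task pen-tablet test battery, so that every stage of
    the pipeline can be exercised and validated without access to
    clinical recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
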