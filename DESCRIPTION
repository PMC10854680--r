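Package: sepsislupi
Title: Sepsis Deterioration Prediction with Privileged Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for predicting short-horizon deterioration of the quick
    Sequential Organ Failure Assessment (qSOFA) score from lead-II ECG and
    electronic health record (EHR) data. Implements taut-string
    approximation of discrete signals inside an epsilon-tube together with
    the six derived morphology features, Butterworth ECG preprocessing,
    ordinal EHR feature assembly over lookback periods, qSOFA scoring and
    instance labeling, a Gaussian-kernel soft-margin SVM baseline and the
    SVM+ classifier for learning using privileged information (LUPI) with
    its one-class dual solver, a synthetic ICU cohort generator, and a
    repeated patient-wise holdout evaluation protocol with grid search on
    validation AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    kernlab,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
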