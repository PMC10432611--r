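Package: longisurv
Title: Longitudinal Chest-CT Survival Modelling with Hybrid CNN-RNN Models
Version: 0.1.0
Authors@R: person("Longisurv", "Developers", role = c("aut", "cre"),
    email = "longisurv@example.org")
Description: Predicts long-term cardiorespiratory mortality from longitudinal
    low-dose chest CT series. Provides a thorax-extraction preprocessing
    pipeline (lung segmentation by thresholding, connected-component and
    convex-hull analysis, intensity normalisation, resampling and affine
    registration), a compact 3D residual convolutional backbone with
    recurrent heads (vanilla, time-aware and time-modulated LSTM cells for
    irregular follow-up intervals), classification and Cox
    proportional-hazards training objectives with sharpness-aware
    minimisation, a two-step cause-specific prediction pipeline, and a full
    survival evaluation stack (AUC, F1, MCC, DeLong comparison,
    Kaplan-Meier stratification, Harrell and IPCW concordance). A synthetic
    longitudinal thorax-phantom generator with Cox-linked, right-censored
    outcomes makes the whole pipeline testable without restricted study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
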