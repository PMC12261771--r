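Package: shockcast
Title: Self-Controlled Shock Prediction from ICU Vital-Sign Waveforms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for predicting circulatory shock one hour ahead from four
    routinely monitored ICU waveforms (arterial blood pressure,
    electrocardiogram, respiration and pulse oximetry) without blood draws.
    Implements shock-event labeling from beat-averaged mean arterial pressure
    and serum lactate, self-controlled observation/control window sampling
    with washout, signal preprocessing (zero-phase ECG band-pass, R-R
    cleaning, arterial-pressure signal-quality masking, breath detection,
    chained-equation imputation), a fixed 299-feature catalog across the four
    modalities including oracle-tested nonlinear complexity metrics (sample
    entropy, Lempel-Ziv complexity, central tendency measure, detrended
    fluctuation analysis and friends), mutual-information feature selection,
    and a six-model classification bench with patient-level bootstrap
    confidence intervals, tree-SHAP importance and logistic confirmation.
    A seedable multi-channel vitals simulator with ground-truth shock events
    and configurable pre-shock physiological drift stands in for credentialed
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp,
    xgboost,
    randomForest,
    ranger,
    glmnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    pROC,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
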