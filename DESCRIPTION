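Package: eegfuse
Title: Multi-Domain EEG Feature Fusion for Discriminating Depression from
    Transient Negative Emotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to discriminate pathological depression from transient
    negative emotion in 8-channel EEG. Implements wavelet-packet
    decomposition based band-power features (alpha/beta PSD ratio),
    normalized frontal alpha asymmetry, and sample entropy; nonparametric
    and parametric feature screening; a lightweight multi-head additive
    attention classifier with single-head and no-attention ablations;
    nested cross-validated SVM, gradient-boosted tree and recurrent
    network baselines; DeLong comparison of correlated ROC curves; and a
    seeded synthetic EEG generator so the whole pipeline is exercisable
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    e1071,
    xgboost,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
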