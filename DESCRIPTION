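Package: neobg
Title: Automated Grading of Neonatal EEG Background Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for automated classification of neonatal
    EEG background activity in intensive-care brain monitoring. Implements
    a preprocessing chain (artifact scanning, Chebyshev II band-pass,
    resampling to 64 Hz, 5-minute epoching with channel/epoch rejection),
    a registry of 98 quantitative EEG features, multi-rater score handling
    (7-to-5 score merger, median smoothing, consensus/all training sets,
    SMOTE balancing), three classifier designs (pairwise linear SVM with
    calibrated posteriors, a two-hidden-layer feed-forward network, and a
    recurrent network trained by real-time recurrent learning) evaluated
    under leave-one-subject-out cross-validation, genetic-algorithm wrapper
    feature selection across artifact-rejection thresholds, agreement
    statistics (Cohen's kappa, macro/weighted accuracy and F1, bootstrap
    confidence intervals), and clinical displays (score-probability heatmap
    and the unidimensional Background Trend). A synthetic neonatal EEG
    generator realizing the clinical scoring definitions (interburst
    interval voltage/duration and amplitude classes) makes the whole
    pipeline testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    S4Vectors,
    SummarizedExperiment,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
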