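Package: ferpredict
Title: Predicting Facial Emotion Recognition Ability from Resting-State
    fMRI Low-Frequency Fluctuation Amplitude
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for individual-level prediction of
    facial emotion recognition (FER) accuracy from resting-state fMRI.
    Computes voxel-wise amplitude of low-frequency fluctuation (ALFF) and
    its globally normalized form (mALFF), maps covariate-adjusted group
    differences with Monte Carlo cluster-extent correction, and predicts
    behavioral accuracy with relevance-filtered leave-one-out
    support-vector regression assessed by permutation testing.  Includes a
    synthetic-cohort generator that plants group amplitude effects and
    brain-behavior coupling so the whole pipeline is testable without
    patient data, plus scoring of visual-search trial logs into FER
    accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
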