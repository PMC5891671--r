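Package: nqikit
Title: Keystroke-Dynamics Biomarker Pipeline for Early Parkinson's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive the neuroQWERTY index (nQi), a keystroke-dynamics
    marker of early Parkinson's disease motor impairment, from raw key
    press/release logs. Implements hold-time extraction with special-key
    filtering, segmentation into non-overlapping 90-second typing windows with
    a valid-window rule, reduction of each window to a 7-component
    variance-centric feature vector, scoring by an ensemble of linear
    epsilon-insensitive support-vector regressors, and the full
    cross-setting validation layer (bootstrap ROC with percentile confidence
    intervals, closest-to-(0,1) cutoffs, Mann-Whitney U, paired DeLong test,
    Bland-Altman agreement, correlation/line-of-best-fit and percentage
    agreement). A seeded synthetic-cohort generator emulates both a
    continuous in-clinic transcription session and sparse bursty at-home
    typing so every pipeline stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
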