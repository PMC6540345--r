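Package: eegcaps
Title: EEG Emotion Recognition with Multiband Feature Matrices and Capsule Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for emotion recognition from multi-channel
    EEG recordings. Trials are segmented into non-overlapping windows, band power
    spectral density (theta, alpha, beta, gamma) is estimated per channel with
    Welch's method and min-max normalized per subject, and the 32-channel features
    are mapped onto a 9x9 scalp-topographic grid per band and tiled into an 18x18
    multiband feature matrix (MFM). A capsule network classifier (convolutional
    front end, primary capsules, dynamic routing by agreement, margin loss and a
    reconstruction decoder) is trained on MFMs and evaluated with k-fold cross
    validation or stratified hold-out, one binary run per affective dimension
    (valence, arousal, dominance). A synthetic EEG generator producing recordings
    in the standard 32-channel affective-computing layout with controllable
    class-dependent band-power effects makes the whole pipeline runnable and
    testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
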