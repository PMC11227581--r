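Package: sonossl
Title: Self-Supervised Audio-Visual-Text Representation Learning for Ultrasound Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of a multi-modal self-supervised
    representation-learning framework for clinical ultrasound video with
    concurrent sonographer speech. Provides a synthetic scan generator with
    full ground truth, an audio cleaning and log-spectrogram front end,
    compact convolutional video/audio/text encoders built on an internal
    reverse-mode autodiff tape, selective information gating over transcribed
    text, correspondence and cross-modal contrastive objectives with
    spatial-aware fusion, transfer tasks (standard plane detection, eye-gaze
    saliency prediction, audio-guided anatomy localisation), and an evaluation
    suite including a saliency-compactness metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
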