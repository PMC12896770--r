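Package: ddkcnn
Title: Mel-Spectrogram CNN Pipeline for Parkinson's Disease Detection from
    Diadochokinetic Speech
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for speech-based discrimination of Parkinson's disease
    (PD) from healthy controls (HC) using diadochokinetic (DDK) recordings.
    Provides a seeded synthetic DDK cohort generator, waveform
    standardization and 160 ms / 50 percent-overlap segmentation, an
    80-band log-Mel spectrogram frontend (80x41 per segment), seven
    waveform- and spectrogram-level data-augmentation operators
    (additive noise, time shifting, SpecAugment, RandMasking, RandMix,
    Cutting Masking, Mixture Masking), a small 2D convolutional network
    implemented in C++, subject-independent training and model-selection
    strategies (train-100 percent, holdout 70/30, best-model and
    mean-model five-fold cross-validation), and confusion-matrix
    reporting at subject level.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
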