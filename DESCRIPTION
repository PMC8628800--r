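Package: sleepstager
Title: Image-Based Sleep-Stage Scoring for Rodent EEG/EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores rodent sleep stages (wake, NREM, REM) from EEG/EMG
    recordings by rendering each scoring epoch as a grayscale image (raw EMG
    trace over a normalized 1-20 Hz power-spectrum heatmap) and classifying
    the images with a VGG-style convolutional network. Includes a Wasserstein
    GAN with gradient penalty for minority-class (REM) augmentation, one- and
    two-epoch image windows with shortened-window variants, a rule-based
    hypnogram smoothing filter for short wake-flanked REM bouts, confusion
    matrix scoring (accuracy, per-class precision/recall/F1, Cohen's kappa)
    with per-subject averaging, and a seeded Markov-chain synthetic EEG/EMG
    generator so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
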