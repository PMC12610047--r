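Package: mmhar
Title: Activity Recognition for Manual Material Handling from Wearable
    Kinematic and sEMG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for classifying manual material handling
    activities (lifting, carrying, placing, holding) from ten fused wearable
    channels: eight joint/segment kinematic signals sampled at 240 Hz and two
    surface electromyography (sEMG) envelopes. Implements the sEMG
    conditioning chain (50 Hz notch, 20-500 Hz Butterworth band-pass,
    rectification, MVC normalization, 250 ms RMS envelope), early channel
    fusion, fixed one-second window segmentation, class balancing by
    down-sampling and Gaussian-noise augmentation, five sequence classifiers
    (BiLSTM, sparse denoising autoencoder, recurrent Sp-DAE, recurrent
    convolutional network, and a DeepConvLSTM benchmark) trained with Adam or
    conjugate gradient, evaluation protocols (stratified 70-30 split,
    subject-increment curves, leave-one-subject-out) scored by macro F1, and
    an analytic network-complexity profiler (learnable parameters,
    multiply-accumulate and multiply-add counts, memory footprint, latency
    estimates). A synthetic session generator emulates the statistical
    structure of manual-handling recordings so the whole stack is testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
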