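Package: lungsound
Title: Respiratory Sound Classification via Parallel Time-Frequency
    Transforms and Hybrid Latent Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auscultation-based detection of pulmonary disease from
    respiratory-cycle recordings. Recordings in the ICBHI-2017 layout (WAV
    audio plus per-recording cycle annotations and a per-patient diagnosis
    table) are segmented into labelled respiratory cycles, zero-padded to a
    fixed six-second duration, and transformed in parallel into a log-mel
    spectrogram and a complex-Morlet continuous-wavelet-transform scalogram.
    Two convolutional autoencoders compress each 128x128 scalogram into a
    2048-dimensional latent vector; the two latents are fused into a hybrid
    feature pool and classified by a single-layer LSTM into binary, three-,
    four- or eight-class respiratory-disease tasks. Includes a seeded
    generator of synthetic ICBHI-layout datasets with crackle and wheeze
    events, the time-stretch/pitch-shift/additive-noise augmentation
    operators, evaluation metrics, and plotting and tidying methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
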