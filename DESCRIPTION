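Package: stteeg
Title: Dual-Stream Spatial-Temporal Transformers for EEG Emotion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies emotions (positive/negative, optionally neutral) from
    multi-channel EEG recordings with a dual-stream transformer. Raw 4-second
    epochs from a 32-channel 10-20 montage are tokenized into electrode-slab
    patches and fed to two weight-independent pre-norm self-attention encoders,
    one ordering tokens along the electrode axis (spatial stream) and one along
    the epoch axis (temporal stream); a layer-normalized linear fusion combines
    the two class-token logit sets. Training uses a weighted composite
    cross-entropy loss and the AMSGrad optimizer, with stratified k-fold
    cross-validation reporting sensitivity, specificity and accuracy. Includes
    overlapped epoching of EDF or delimited-text recordings, a class-conditional
    synthetic EEG generator (1/f background plus band-limited oscillations) for
    end-to-end testing without access to private corpora, and ablation runners
    over the loss weight, the two streams, and the heads-by-layers grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
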