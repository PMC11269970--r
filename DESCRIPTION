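Package: bowelspot
Title: Multiscale Bowel Sound Event Spotting in Continuous Abdominal Audio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects sparse bowel-sound events in continuous 16 kHz
    abdominal audio recordings. Implements the full spotting pipeline:
    high-pass filtering and 10-second segmentation, log-Mel spectrogram
    features, an Efficient-U-Net (EfficientNet encoder with a U-Net style
    decoder) that labels each 25 ms spectrogram frame, training with a
    combined cross-entropy and dice objective plus SpecAugment-style
    augmentation, frame-mask to event decoding, and an evaluation suite
    for highly imbalanced audio (samplewise precision/recall, two-class
    segment timing-error taxonomy, SNR- and duration-conditioned metrics,
    and class-imbalance ratio sweeps). A synthetic corpus generator
    emulating the sparsity, duration and SNR statistics of wearable
    auscultation recordings makes the pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
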