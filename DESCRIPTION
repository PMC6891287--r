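Package: cspcwt
Title: Common Spatial Pattern and Wavelet Scalogram Decoding of Grasp-and-Lift EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes six grasp-and-lift motor events (handstart, grasp, lift, hold,
    replace, release) from multichannel EEG sampled at 500 Hz. Implements equiripple
    FIR band-pass filtering to the 7-30 Hz mu/beta band, common spatial pattern (CSP)
    spatial filtering with a one-vs-rest multiclass extension, analytic Morse wavelet
    scalogram imaging (grayscale, bicubic 224x224 resize, RGB electrode-triad stacks),
    a pluggable image classification stage with a small self-contained reference
    convolutional network, and ROC/AUROC evaluation. A synthetic EEG generator with
    class-specific spatial mixing and physiological artifact models makes the full
    pipeline testable without any recorded dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
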