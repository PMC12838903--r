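Package: eeglwf
Title: Cross-Subject Emotion Recognition from Sparse-Channel EEG with
    Learning without Forgetting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-subject valence/arousal decoding from
    sparse-channel (four prefrontal electrodes) EEG. Provides a synthetic
    EEG generator with class-conditional frontal alpha asymmetry and
    controllable inter-subject shift, a preprocessing pipeline (resampling,
    baseline removal, Butterworth band-pass filtering, channel selection,
    windowing, per-window normalization, label derivation), a multi-scale
    spatio-temporal convolutional network trained with mini-batch Adam,
    subject-incremental adaptation by Learning without Forgetting
    (temperature-scaled knowledge distillation against a frozen teacher),
    leave-one-subject-out evaluation with accuracy, F-score and confusion
    matrices, ablation variants, and an incremental-size sweep. All heavy
    numerics are vectorized over BLAS; no external deep-learning runtime
    is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    data.table,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
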