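Package: pcgscreen
Title: Heart-Failure Screening from Phonocardiograms with Gated Recurrent Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete pipeline for three-class heart-failure screening
    (normal, HFpEF, HFrEF) from phonocardiogram (heart-sound) recordings.
    Includes a labeled synthetic phonocardiogram simulator, WAV and
    onset-sidecar input/output, anti-aliased resampling to a 600 Hz working
    rate, S1-onset localization with a duration-dependent four-state hidden
    semi-Markov model using logistic-regression emissions over envelope
    features, period-synchronous fixed-length framing with min-max
    normalization, gated recurrent unit (GRU) and LSTM sequence classifiers
    trained by backpropagation through time with Adam, a fully convolutional
    network and a feature-plus-SVM baseline, and a tenfold cross-validation
    harness with confusion-matrix metrics and hyperparameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    pracma,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
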