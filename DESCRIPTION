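Package: eegcomplexity
Title: Multiband Non-Linear Complexity Analysis of Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for awake resting-state EEG "brain complexity"
    analysis: discrete-wavelet (biorthogonal 3.5) decomposition of 5-second
    windows into the five canonical EEG sub-bands, ten non-linear feature
    estimators (correlation dimension, largest Lyapunov exponent, approximate
    entropy, rescaled-range Hurst exponent, detrended fluctuation analysis,
    Higuchi and Katz fractal dimensions, energy, Shannon and log-energy
    entropies), pairwise-group z-score normalization, and a channel-by-sub-band
    leave-one-out classification grid over a fixed suite of sixteen classifier
    presets. Includes a seeded synthetic EEG cohort generator with controlled
    spectral content, long-memory structure and injectable group effects, so
    every stage is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    rpart,
    deSolve,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
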