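Package: gwovmd
Title: Grey-Wolf-Optimized Variational Mode Decomposition for EEG Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes single-channel EEG-style time series into narrowband
    intrinsic mode functions by variational mode decomposition (VMD), selects
    the VMD hyperparameters (mode count K and penalty factor) per analysis
    epoch with a grey wolf optimizer minimizing a signed envelope-entropy
    fitness, and post-processes modes with Hilbert-transform envelope,
    instantaneous-frequency and time-frequency (Hilbert spectrum) analysis.
    Includes readers for plain-text sample streams, epoch segmentation,
    synthetic multi-tone and anesthesia-EEG generators, per-epoch pipelines
    with before/after-emergence summaries, broom-style tidiers and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    signal,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
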