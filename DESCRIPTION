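Package: pulseHHT
Title: Hilbert-Huang Analysis and Random-Forest Recognition of Arterial Pulse Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-channel radial-pulse pressure
    recordings as nonstationary time series. Implements empirical mode
    decomposition (EMD) with cubic-spline envelopes and mirror boundary
    extension, per-mode analytic-signal (Hilbert) traces and Hilbert
    spectra, intrinsic-mode-function energy and sample-entropy feature
    extraction, nonparametric rank-sum comparison of two cohorts, and a
    random-forest recognition experiment over energy, entropy and combined
    feature sets. A synthetic pulse-waveform generator produces labelled
    two-cohort data sets with configurable effect structure so the whole
    pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
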