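Package: oddballmmn
Title: Duration-Oddball Mismatch Negativity Simulation and Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates multichannel auditory oddball EEG cohorts with known
    ground truth, preprocesses them (decimation, Chebyshev band-pass, bad-channel
    detection and spherical spline interpolation, epoching, two-stage amplitude
    rejection, baseline correction, temporal-site re-referencing, ocular template
    regression), extracts duration mismatch-negativity (MMN) amplitudes at a
    frontal composite in the 200-240 ms window, and runs the associated group
    statistics: linear mixed-effects models, planned deviant-vs-standard
    contrasts, spatio-temporal cluster-based permutation tests (maxsum),
    JZS Bayes-factor paired t-tests, and bootstrap Spearman correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    lmerTest,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
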