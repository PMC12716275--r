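Package: sleepwarp
Title: Dynamics of Longitudinal Sleep EEG: Warping, Oscillations and
    Transition Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of longitudinal sleep EEG recorded over many
    consecutive nights. Decomposes recordings into five-band multitaper
    power series, quantifies night-to-night dissimilarity with open-ended
    dynamic time warping, extracts archetypal nights by DTW barycenter
    averaging, detects sleep spindles and slow waves with their phase
    coupling, and forecasts NREM-REM stage transitions with point-process
    generalized linear models. Includes a synthetic multi-subject cohort
    generator reproducing the statistical structure these analyses assume,
    so the full pipeline is testable without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    pROC,
    signal,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
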