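Package: startreact
Title: Fractionation Analysis of StartReact Electromyographic Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured multi-muscle surface EMG
    experiments comparing movements cued by quiet versus loud (startling)
    auditory stimuli. Provides rectified-EMG onset detection (baseline mean +
    3 SD thresholding) and earliest-reaction-time (eRT) extraction,
    eRT-referenced window-mean activation features, matched trial exclusion,
    per-condition covariance eigendecomposition with cumulative
    percent-variance-explained (CPVE) curves averaged over repeated random
    exclusions, an exhaustive within-subject shuffle test for CPVE differences
    with family-wise false-positive calibration, cosine-similarity analysis of
    muscle activation patterns, and a synthetic EMG experiment generator with
    known ground truth (onsets, synergy rank, cue effects) for validation and
    power analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    nortest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
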