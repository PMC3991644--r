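Package: fricshape
Title: Fricative Place-of-Articulation Classification from Short-Time Spectral Features
Version: 0.1.0
Authors@R:
    person("Fricshape", "Developers", email = "fricshape@example.org", role = c("aut", "cre"))
Description: Classifies fricative consonants into three place-of-articulation
    groups (non-sibilant, alveolar, palatal) from single 8-ms analysis frames,
    in quiet and in noise. Provides TIMIT-style corpus input/output, RMS level
    equalization, speech-shaped-noise and multi-talker-babble maskers mixed at
    exact signal-to-noise ratios, nine frame-level spectral feature sets
    (spectral moments, peak and slope, MFCCs, gammatone filterbank outputs,
    raw FFT magnitudes), linear and kernel principal component reduction, a
    one-vs-one C-SVC support vector classifier with radial basis kernel and
    cross-validated grid search, majority-vote sequence decoding, confusion
    matrix and Kruskal-Wallis evaluation utilities, and a calibrated synthetic
    fricative corpus generator so the full pipeline is testable without
    licensed speech recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
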