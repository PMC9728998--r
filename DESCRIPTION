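Package: vnseeg
Title: Phase-Lag-Index Connectivity and Aperiodic Spectral Analysis of
    Resting EEG for Vagus Nerve Stimulation Outcome Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing multichannel resting-state EEG in
    neuromodulation outcome studies. Implements phase lag index (PLI)
    functional connectivity with global, regional and channel-level
    aggregation on a 61-channel 10-10 montage; estimation of the aperiodic
    (1/f^chi) offset and exponent of the power spectrum by robust
    peak-excluding log-log regression; frequency-domain band filtering with
    raised-cosine transitions; common-average referencing; a 16-bit European
    Data Format (EDF) reader and writer; nonparametric pre/post group
    statistics (Mann-Whitney U, Benjamini-Hochberg FDR families, Cohen's d,
    Spearman correlation with the Labar seizure-reduction index); and a
    synthetic-EEG cohort generator with known ground-truth coupling and
    spectral parameters for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
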