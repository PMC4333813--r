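Package: spindler
Title: Two-Phase Sleep Spindle Detection from Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic detection of sleep spindles in multichannel scalp
    EEG. A sensitivity phase segments the recording into events at local maxima
    of the continuous wavelet transform ridge (generalized Morse wavelets) over
    the 10-16 Hz band and selects candidates whose ridge amplitude and sigma
    index both exceed percentile thresholds derived from a REM-sleep null
    distribution. A specificity phase clusters the selected candidates on
    normalized frequency and anterior-posterior scalp position with
    average-linkage hierarchical classification, cuts the dendrogram by a
    class-size ratio rule, and keeps the classes covering most expert-scored
    spindles. Includes by-event evaluation metrics, p-value sweep curves,
    sleep-cycle accounting, a partial-scoring bootstrap, and a seeded synthetic
    polysomnogram generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
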