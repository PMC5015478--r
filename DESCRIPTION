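Package: mmnrubberband
Title: Parameterization and Correlation Analysis of Mismatch Negativity Waves
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for mismatch negativity (MMN)
    difference waves recorded in passive auditory oddball paradigms. Generates
    synthetic epoched EEG with known ground-truth MMN morphology and a
    configurable amplitude-downslope coupling ("rubberband" vs. null mode),
    processes epochs into baseline-corrected, low-pass filtered
    deviant-minus-standard difference waves, extracts nine waveform parameters
    (peak amplitude, averaged peak amplitude, onset, offset, peak latency,
    duration, area, upslope, downslope) with a baseline-derived threshold and
    fake-MMN rejection, and runs electrode-wise Spearman correlation counting
    plus region-of-interest analyses across inter-stimulus-interval conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
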