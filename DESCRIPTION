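Package: eegbench
Title: Benchmarking EEG System Quality in Stationary and Mobile Recordings
Version: 0.1.0
Authors@R:
    person("EEG", "Bench", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking electroencephalography (EEG) acquisition
    systems with an auditory P300 oddball task recorded while seated and while
    walking. Implements the full epoching and artifact-rejection pipeline
    (zero-phase high-pass and notch filtering, bad-channel interpolation,
    behavioral false-positive/false-negative rejection, sliding-window
    peak-to-peak amplitude thresholding with 75-400 microvolt sweeps and
    matched-count rejection across conditions) and a quality-metric suite:
    pre-stimulus noise (PSN), band power and walking/seated power ratios, P300
    signal-to-noise ratio, single-trial coefficient of variation (CV_ERP),
    scalar-product ERP similarity with Fisher-domain averaging, test-retest
    intraclass correlation, and Cohen's d. A synthetic oddball-session
    simulator (P300 template, 1/f background, alpha rhythm, gait-locked
    artifact, blinks) makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
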