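Package: vwplat
Title: Resampling-Based Onset Latency Analysis for Visual-World Eye-Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates and compares effect-onset latencies between groups in
    visual-world-paradigm eye-tracking time courses. Implements four onset
    latency measures (consecutive significant bins and Holm-Bonferroni-based
    measures, each with an optional effect-size threshold), by-participant and
    stratified bootstrap resampling with five confidence interval constructions
    (percentile, normal, empirical, bias-corrected, and accelerated
    bias-corrected), a participant-level permutation test, and a Monte Carlo
    engine that evaluates power, Type I error, and coverage of these
    procedures. A synthetic gaze-data generator emulating infrared and webcam
    sampling regimes makes every procedure testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    withr
Config/testthat/edition: 3
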