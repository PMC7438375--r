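Package: actbind
Title: Action-Binding Analysis for Libet-Clock Timing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for action-binding experiments in which
    participants report the time of a voluntary keypress on a rotating
    Libet clock while keypress force is recorded with a force sensing
    resistor. Covers force-sensor calibration (monotone polynomial raw
    unit to Newton conversion), per-trial feature extraction (reported
    keypress time, peak force and peak-force latency), the standard
    trial-rejection cascade and participant exclusion rules, robust
    skipped Pearson correlations with percentile-bootstrap confidence
    intervals, binding quantification via per-participant two-sample t
    statistics and group-level paired tests, 2x2 within-subject ANOVA
    with partial eta squared, report-precision analysis, and a
    participant-resampling bootstrap power analysis. A synthetic-data
    generator built on a force-weighted multisensory cue-integration
    model of reported action time makes the whole pipeline testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    nortest,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
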