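Package: decalage
Title: Working-Memory Load Estimation and Probe-Tone ERP Analysis for
    Simultaneous Interpreting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates instantaneous working-memory load during simultaneous
    interpreting from time-coded source/target transcripts under three
    weighting schemes (content words, corpus-frequency weighted content words,
    and syllable-weighted words), aligns the piecewise-linear load series to
    task-irrelevant auditory probe tones, labels probe-locked EEG epochs by
    per-subject load quantiles, extracts P1/N1 window-mean amplitudes and peak
    latencies, and tests load and direction effects with an exact Wilcoxon
    signed-rank test and repeated-measures ANOVA with Greenhouse-Geisser
    correction plus leave-one-out jackknife. Includes a synthetic-data
    generator (transcripts, probe trains, forward-modelled EEG with known
    modulation slopes) so the full pipeline is testable with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
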