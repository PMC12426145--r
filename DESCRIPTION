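Package: spinfill
Title: Fill-In and Infill Analysis for Serial Recall with Same, Spun, and
    Scrambled Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the fill-in tendency in serial-order memory.
    Builds same, spun (rotated), and scrambled (Williams balanced Latin
    square) list sets for serial learning experiments; scores trial-level
    recall output into correct, anticipation, postponement, repeat,
    intrusion, and omission responses with a per-participant false-start
    screen; computes overall and postanticipation lag-conditional response
    probability (lag-CRP) curves under repeat-scored and repeat-excluded
    policies; summarises fill-in and infill rates and their error ratio;
    and runs the associated paired and independent t tests, one-way ANOVAs,
    and default-prior (JZS) Bayes factors. A generative simulator of serial
    recall with positional and chaining retrieval cues, a primacy gradient,
    response suppression, omissions, intrusions, and response-time
    structure (including false starts) provides fully synthetic data so
    every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
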