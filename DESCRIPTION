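Package: gazeclust
Title: Spatio-Temporal Analysis of Horizontal Gaze Bias in Free Visual
    Exploration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing overt attentional orienting in eye-tracking
    free-visual-exploration experiments with repeated stimulation sessions.
    Provides fixation-table input/output with screen-geometry aware
    pixel/degree conversion, velocity-acceleration event detection,
    saliency-balanced block assignment, linear mixed-model analyses of the
    average horizontal gaze position (pre-post and baseline-covariate
    parameterisations, Satterthwaite F-tests, Bonferroni post-hocs), and a
    cluster-mass permutation analysis of 100-ms gaze-position time-bins with
    a max-mass family-wise error correction. A synthetic scanpath generator
    with injectable condition-by-timepoint effects makes every stage testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    lme4,
    lmerTest,
    emmeans,
    car,
    yaml,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
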