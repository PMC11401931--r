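Package: laminardyn
Title: Layer-Specific Trial Timecourse Estimation, Temporal Cross-Decoding
    and Permutation Inference for Laminar fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing layer-resolved (laminar) fMRI of
    event-related working-memory tasks: a synthetic laminar BOLD generator
    with known ground-truth effects, equidistant cortical-depth binning,
    finite-impulse-response (tent-basis) trial timecourse estimation with
    polynomial detrending and percent-signal-change scaling, layer-wise
    univariate period contrasts with paired statistics, trial-normalized
    temporal decoding and temporal cross-decoding with transition-balanced
    cross-validation folds and linear support vector machines, and
    permutation-based inference (subject and population null distributions,
    1-D and 2-D cluster tests, dynamic-coding conjunction masks, and a
    permutation repeated-measures ANOVA). A pipeline driver runs the whole
    analysis from a single configuration on synthetic or externally
    supplied NIfTI + events data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
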