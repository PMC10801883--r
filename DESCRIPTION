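Package: gazemorph
Title: Landmark-Based Gaze Morphing and Fixation-Pattern Analysis for
    Free-Viewing Eye Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured free-viewing eye-tracking
    experiments with face stimuli: velocity-threshold saccade detection and
    saccadic main-sequence fitting; piecewise-affine morphing of gaze positions
    onto an average face shape built from 26-point landmark correspondences
    (Delaunay triangulation, per-triangle affine maps); fixation heatmaps with
    Gaussian smoothing and analysis-resolution resampling; dwell-time
    region-of-interest statistics with baseline normalization, a heatmap
    pattern change index, and permutation inference with Benjamini-Hochberg
    correction; plus a fully seeded synthetic scanpath generator with ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deldir,
    sp,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
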