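Package: openfieldr
Title: Spatial-Coding Analysis of Single Neurons in Open-Field Navigation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-neuron spatial coding recorded while
    an animal navigates an open-field arena with a goal zone and a movable
    visual cue. Provides a synthetic session generator (goal-biased foraging
    trajectories and inhomogeneous-Poisson spike trains from grid, border,
    non-grid spatial, head-direction, center-bearing, center-distance,
    conjunctive, and landmark-modulated tuning models), behavioral zone
    statistics, firing-rate maps and tuning curves, a penalized Poisson GLM
    with cross-validated forward model selection for cell classification,
    grid/border/spatial-information scores, egocentric-bearing reference-point
    (MVL) maps, spike-shift shuffle significance thresholds, and circular
    statistics for cue-rotation and cue-duplication experiments
    (preferred-direction shifts, bidirectionality index, bidirectional
    von Mises fits, rotated-map correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
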