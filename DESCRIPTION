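Package: adaptreg
Title: Deformable Image Registration and Contour Propagation for Adaptive
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("adaptreg", "developers", email = "adaptreg@example.org",
           role = c("aut", "cre"))
Description: Tools for propagating regions of interest (ROIs) from a
    planning CT scan to a per-treatment scan in adaptive radiotherapy.
    Implements two deformable image registration algorithms - a
    multi-resolution fast symmetric demons method driven by optical-flow
    forces, and a salient-feature-based method that matches scale-attributed
    interest points by local correlation and interpolates them with
    thin-plate splines - together with rigid pre-registration, histogram
    matching, mask and mesh contour propagation, contour-agreement metrics
    (Dice score, mean slicewise Hausdorff distance, centre-of-mass
    displacement), expert-score summaries and study-level statistics
    (one-way ANOVA, point-biserial correlation). A synthetic CT-like phantom
    generator with analytically known deformations supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
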