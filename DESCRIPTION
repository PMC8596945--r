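Package: escimap
Title: Standardized Effect-Size Maps with Exact Confidence Intervals for
    fMRI Group Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise standardized effect sizes (Hedges' g) and
    their exact noncentral-t confidence intervals from group-level t-statistic
    maps produced by general linear model analyses of functional MRI data.
    Supports one-sample, two-sample and arbitrary GLM contrast designs via the
    contrast variance scale sqrt(c'(X'X)^-c). On top of the effect-size maps it
    provides three confidence-interval-based inference procedures: maps of
    undecidability (voxels statistically indistinguishable from a detected
    cluster's reference effect), voxel-wise replication testing against a
    reference sample, and lateralization testing against a mirrored cluster
    reference. A built-in simulator generates two-group slice data with known
    localized standardized effects for validation and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
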