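Package: bodygeom
Title: Representational Geometry of Body-Part Maps in Visual Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for block-design fMRI studies of
    the body-part code in lateral occipitotemporal cortex (LOTC). Generates
    synthetic cohorts of run-wise voxel patterns with a three-category
    (action-effector / face / non-effector) cluster structure, fits first-level
    general linear models with a canonical double-gamma haemodynamic response,
    extracts sphere ROIs, builds split-half representational dissimilarity
    matrices (1 - Pearson r), and tests representational geometry with an
    exhaustive 420-partition ANOSIM permutation test, Mantel matrix
    correlation, within/between-group similarity ANOVA, Spearman trait
    correlations, and three-class linear-SVM decoding with leave-one-run-out
    cross-validation and bootstrap class balancing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
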