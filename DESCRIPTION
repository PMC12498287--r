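Package: thalscn
Title: Seed-Based Structural Covariance Networks of Thalamic Subfields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mass-univariate seed-based structural covariance network (SCN)
    analysis of thalamic subfields for voxel-based morphometry data, aimed at
    lesion studies such as chronic capsular stroke. Fits a per-voxel general
    linear model with group-specific covariance slopes between a z-scored seed
    (thalamic subfield) volume and gray-matter volume, tests the slope-difference
    contrast with cluster-extent family-wise-error control by Freedman-Lane
    permutation, handles lesion masking and lesion probability maps, extracts
    atlas-overlap regions of interest with post-hoc models, compares subfield
    volumes between groups with FDR control, and screens Spearman partial
    correlations against clinical scores. A synthetic-cohort generator with a
    full ground-truth record supports calibration and parameter-recovery
    testing of every stage.
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
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
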