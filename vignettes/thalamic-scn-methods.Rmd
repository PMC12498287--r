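---
title: "Seed-based structural covariance of thalamic subfields: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based structural covariance of thalamic subfields: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thalscn)
library(dplyr)
```

## The question and the model

A structural covariance network (SCN) asks whether the volume of a seed
structure co-varies, across subjects, with gray-matter volume (GMV)
elsewhere in the brain. In a lesion cohort the interesting quantity is the
*group difference* in that covariance: after a capsular stroke, do the
thalamic nuclei reorganize their covariance with remote cortex?

`thalscn` fits, at every voxel $v$,

$$
\mathrm{GMV}_v = \beta_1 \mathrm{Label}_{cs} + \beta_2 \mathrm{Label}_{nc}
 + \beta_3 \mathrm{SeedVol}_{cs} + \beta_4 \mathrm{SeedVol}_{nc}
 + \textstyle\sum_x \beta_x \mathrm{Confounder}_x + \varepsilon
$$

where the two label columns are group indicators (so $\beta_1, \beta_2$ are
group mean GMV), SeedVol is the z-scored volume of one thalamic subfield
split into group-specific columns (zero for subjects of the other group),
and the confounders are mean-centred age, gender (male = 0), scanner
(K−1 dummies, reference = first level alphabetically) and mean-centred
total intracranial volume. $\beta_3$ and $\beta_4$ are the group-specific
covariance slopes; the contrast $[\beta_3 - \beta_4]$, tested with
$t = c'\hat\beta / \sqrt{\hat\sigma^2\, c'(X'X)^{-1}c}$ on $n - p$ degrees
of freedom, is the group difference in covariance connectivity.

Seed volumes are z-scored over the *pooled* sample. Standardizing within
group would rescale each slope by its own group's volume dispersion and
change what the contrast means; a `zscore_scope = "per-group"` flag exposes
the alternative for sensitivity analysis only.

Inference is directional by default (`direction = "greater"` tests
CS > NC; the reverse and a two-sided variant are flags), matching the
convention by which "increased covariance" findings are reported as
one-tailed t-contrasts at voxelwise p < 0.001.

## Lesion handling

Patients' lesions are binary masks on the analysis grid. Two operations
cover the standard workflow: `lesion_probability_map()` (the voxelwise
fraction of patients lesioned there) and `lesion_exclusion_mask()`, which
removes from the analysis mask every voxel lesioned in *any* patient.
Excluding the union — rather than treating lesioned voxels as per-subject
missing data — keeps the design matrix and degrees of freedom identical at
every voxel, at the price of discarding some normal tissue in controls.

## Cluster-extent FWE by constrained Freedman–Lane permutation

Parametric cluster correction needs random-field smoothness estimation;
this package instead controls the family-wise error nonparametrically.
Suprathreshold voxels (voxel p < 0.001 by default) are grouped into
connected components under 18-connectivity (faces + edges, the common
neuroimaging convention; 6 and 26 are flags), and each observed cluster's
extent is referred to the permutation distribution of the *maximum* null
cluster extent:

1. Fit the model **constrained to the contrast's null hypothesis**
   $\beta_3 = \beta_4$ — i.e. group means, confounders, and one *common*
   covariance slope.
2. Permute the rows of the constrained-model residuals, add them back to
   the constrained fit, refit the full model, threshold, and record the
   maximum cluster extent.
3. $p_{FWE} = (1 + \#\{\text{permuted max} \ge \text{extent}\}) / (B + 1)$,
   so p can never be zero and the smallest attainable value is $1/(B+1)$
   (a warning fires if $B$ is too small for the requested level).

The constrained reduced model is the important design choice. Both groups
genuinely covary with the seed (the null hypothesis is *equal* slopes, not
*no* slopes). Residualizing against group means and confounders alone
would leave the common covariance in the residuals; under permutation it
re-aligns with the seed coherently across whole regions, inflating the
null max-extent distribution and costing most of the power against real
slope differences. Constraining instead to $\beta_3 = \beta_4$ exchanges
only the differential association — the quantity under test — while the
calibration under a true null is unchanged (verified by the Monte-Carlo
calibration tests: the fraction of null cohorts with any FWE-significant
cluster stays at the nominal 5%).

Voxels whose residual variance is numerically zero (constant GMV, or a
noise-free fixture fitted exactly) get `t = NaN` and never enter clusters.

## ROI extraction and post-hoc models

From the FWE-significant clusters of all seeds the package follows the
five-step atlas-overlap recipe: binarize each seed's significant map,
union them, intersect the union with an integer-labelled parcellation,
select every region whose overlap ratio (intersection voxels / region
voxels — the *region* is the denominator) **strictly exceeds** 10%, and
extract each subject's mean GMV over each selected region (on the
lesion-excluded mask, so lesioned voxels never enter a mean). Ratio
exactly at threshold is *not* selected; the boundary is unit-tested.
The same covariance model is then refit with each ROI mean as the
response, Bonferroni-adjusted over all (seed, ROI) pairs actually tested —
the published family is unstated, so the family is everything tested here.

## Subfield volume comparison and behavioural screen

`compare_subfield_volumes()` fits `volume ~ group + age + gender +
scanner + tiv` per (hemisphere, subfield) and applies Benjamini–Hochberg
FDR over the pooled family of 50 tests (a per-hemisphere option exists).
Note a consequence of FDR control worth keeping in mind when reading
"all ipsilesional, no contralesional" patterns: with 25 strong true
positives in the family, BH admits a contralesional false positive with
appreciable probability per cohort (expected count ≈ $q/(1-q) \times 25
\approx 1.3$); the tests assert the attainable version of the pattern
(all 25 ipsilesional detected; contralesional rejections within the
FDR-implied bound, median zero).

The behavioural screen computes Spearman partial correlations (ranks of
x, y and covariates; covariate ranks regressed out; t-approximation on
$n - k - 2$ df) between per-seed SCN measures and clinical scores within
one group, controlling age, gender and scanner, with BH-FDR over the full
seed × metric grid and a looser uncorrected tier tallied per metric and
per seed. Missing scores are pairwise-deleted, never imputed, and
`n_effective` is reported per pair.

A group-level covariance has no per-subject value, so the screen needs an
operationalization: the default subject-level measure is the ROI-mean GMV
times the subject's z-scored seed volume — the cross-term whose group mean
is the covariance slope the GLM estimates. This interpretive choice is
isolated in `scn_subject_measure()` (with `"roi_mean"` as the documented
alternative) so it can be swapped without touching the screen.

## The synthetic cohort generator

Real MRI for such a cohort is not redistributable, so every stage is
validated against `simulate_cohort()`, which generates data with exactly
the structure the model assumes, plus a `truth` record of everything
planted:

* **Cohort**: 45 CS / 93 NC by default, three scanners, age ≈ 55.5 ± 7.4,
  TIV ≈ 1.45 ± 0.13 L — the study's margins.
* **Subfield volumes**: 25 nuclei per hemisphere at plausible FreeSurfer
  scales, 10% coefficient of variation, inter-subfield correlation 0.5 via
  a shared latent factor; CS ipsilesional volumes reduced by the `atrophy`
  fraction (default 10%).
* **GMV**: baseline 10 (arbitrary concentration units) + additive
  age/gender/scanner/TIV effects + group-specific slope × z(seed volume)
  inside box-shaped effect blobs + Gaussian noise smoothed to 6 mm FWHM
  (FFT convolution, periodic boundary, kernel normalized so `noise_sd` is
  the post-smoothing marginal SD). Defaults: slopes (2, 1) and
  `noise_sd = 1`, i.e. contrast signal-to-noise
  $(\beta_3 - \beta_4)/\sigma = 1$.
* **Lesions**: one box per patient (~0.1 mL at the default geometry) near
  the right internal-capsule location of the miniature grid, jittered per
  patient, zeroing GMV. Zeroing rather than deleting keeps the stack
  rectangular; exclusion is the analysis mask's job, as in the real
  pipeline.
* **Clinical scores**: group means/SDs on each instrument's scale
  (FMA ceiling 100, accuracies clipped to [0, 1], reaction times
  positive), plus weak default links to z-scored subfield volumes — the
  emulated cohort shows no FDR-surviving brain–behaviour association,
  only uncorrected trends.

Two generator choices deserve their rationale spelled out. First,
smoothing is applied to the *noise only*; effect blobs stay block-shaped,
so the planted slopes are exactly recoverable (on a noise-free cohort the
fitted $\beta_3, \beta_4$ equal the planted 2 and 1 to numerical
precision — a sharp parameter-recovery test that smoothed effects would
blur). Second, the default effect blob is 5×5×5 voxels (≈ 0.42 mL at
1.5 mm): cluster-extent inference has power only for effects larger than
the suprathreshold islands the smoothed noise throws up by chance
(extents up to ~30 voxels at p < 0.001 on this grid with 6 mm FWHM), and
real covariance clusters span gyri, i.e. the mL scale — a 27-voxel
(0.09 mL) effect would be both unrealistic and right at the null's
detection floor.

What the generator does *not* emulate: anatomy (tissue classes, template
registration, folding), scanner artifacts beyond an additive offset,
non-Gaussian or spatially non-stationary noise, and lesion-correlated
covariance disruption (lesions and effect blobs are placed independently).
A passing suite therefore demonstrates that the *statistics* are correct
under the model's own assumptions — calibrated error rates, exact
parameter recovery, oracle-equivalent estimation — not that the pipeline
is robust to real-data violations of those assumptions.

## Problem sizes and numerical choices

The default grid is 16×16×16 at 1.5 mm — a miniature whole-brain stand-in
chosen so a full simulate–fit–permute–select–refit cycle at study scale
(n = 138, B = 500 permutations) completes in seconds and the calibration
Monte-Carlos (50–100 cohorts) in minutes; everything scales up by
configuration. The smoothness property (empirical FWHM within 20% of the
requested 6 mm, estimated from the lag-1 autocorrelation) is checked on a
48³ grid where the autocorrelation estimate is stable.

Other numerics: affine agreement tolerance 1e-4 mm (header jitter below
physical meaning); voxel indices are reported 0-based with world
coordinates via the NIfTI affine; hemispheres map right = ipsilesional
(a right-hemisphere-lesion cohort); the degenerate all-tied Mann–Whitney
sample returns Z = 0; constant vectors are rejected by `zscore()`, the KS
screen, and the correlation routines rather than silently propagated; the
KS normality screen uses the sample's own mean and SD and is therefore
conservative (the Lilliefors situation) — it is a routing heuristic for
the demographics table, not strict inference.

## Known limitations

* Cluster-extent permutation exchanges residual *rows*, assuming
  exchangeable subjects; scanner-specific residual covariance would
  violate this (a within-scanner permutation scheme would be the fix).
* The per-subject SCN measure feeding the behavioural screen is an
  operationalization, not a published definition; conclusions from it
  should be checked against the `"roi_mean"` alternative.
* The generator's lesions zero GMV instead of deforming it; real lesions
  bias segmentation in their penumbra, which masking does not fully
  remove.
* Welch summaries reproduce published t statistics only to the precision
  of the printed means/SDs.
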