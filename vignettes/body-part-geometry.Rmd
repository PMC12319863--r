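---
title: "Testing the three-category geometry of body-part representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing the three-category geometry of body-part representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodygeom)
```

## The scientific question

High-level visual cortex on the lateral occipitotemporal surface (LOTC)
responds selectively to bodies and body parts. A recurring claim about this
region is that its multivoxel response patterns to individual body parts are
not organized part-by-part but fall into three functional clusters: *action
effectors* (hand, foot, arm, leg), *faces* (upper face, lower face), and
*non-effector* body parts (chest, waist). `bodygeom` implements a complete,
testable pipeline for this claim — from a block-design fMRI forward model
through first-level GLM estimation, split-half representational dissimilarity
matrices (RDMs), an exhaustive-permutation ANOSIM test of the three-cluster
hypothesis, Mantel comparisons between groups (a typically-developing-like
and an autism-spectrum-like cohort), and three-class linear-SVM decoding —
driven entirely by a synthetic-cohort generator, since no participant data
are available for this design.

## The generative model

`cohort_config()` fixes the study conditions. Each synthetic subject receives:

* one mean voxel pattern per category, drawn standard normal per voxel and
  scaled by `category_separation`. Drawing the means from a continuous
  distribution guarantees voxel-level variance, so every Pearson correlation
  downstream is well defined;
* a condition-specific offset pattern scaled by `condition_separation`,
  placing the 8 body-part conditions around their category means;
* i.i.d. Gaussian run noise of SD `run_noise_sd` on every beta, which is what
  makes the odd/even split-half correlation informative;
* for ASD-like subjects, a uniform `group_shift` (default 0, i.e. both groups
  share one generative geometry — the relevant null for the between-group
  comparisons).

The whole-body and chair conditions carry their own mean patterns, with the
chair mean set to the negative of the whole-body mean and a uniform
`localizer_amplitude` added to whole body and subtracted from chair. This
makes the whole-body-versus-chair contrast the textbook localizer: positive
everywhere in the ROI, with the two localizer conditions maximally dissimilar.
Both are excluded from all representational analyses, which use only the 8
body parts.

Default numeric choices: `category_separation = 1`, `condition_separation =
0.5`, `run_noise_sd = 0.5`. At these values a 23-subject group recovers the
three-cluster geometry reliably while single subjects remain noisy — the
regime the analysis is designed for. The acceptance computation instead uses
the deliberately extreme noiseless regime (`category_separation = 5`,
`condition_separation = 1`, `run_noise_sd = 0`), where the hypothesized
partition must strictly dominate every structurally distinct alternative.

Trait scores (age, FSIQ, SRS, AQ, four sensory-profile subscales) are drawn
from group-specific normal distributions matching the demographic profile the
cohort emulates (e.g. AQ 16.0 ± 7.0 TD-like vs 33.0 ± 5.0 ASD-like). They
are independent of the neural patterns by default; an optional `coupling`
argument mixes a per-subject neural score into every trait so that
brain–trait correlation recovery can itself be tested.

What the generator does *not* emulate: anatomy, retinotopy, spatial noise
correlations, scanner artifacts beyond low-frequency drift and AR(1) noise,
or subject motion coupled to the signal. Passing tests therefore demonstrate
the correctness and calibration of the *analysis*, not properties of real
LOTC data.

## Design and first-level GLM

One run is 20 task blocks (10 conditions × 2 repetitions) of 12 s each, with
fixation baselines of 27 s before the first block, 12 s after blocks 5, 10
and 15, and 15 s after block 20: 318 s = 106 volumes at TR 3 s
(`build_run_design()`). Boxcars are built on a 0.1 s microtime grid,
convolved with the canonical double-gamma HRF (response/undershoot delays
6/16 s, dispersions 1/1, ratio 6, 32 s kernel — the conventional
parameterization), and sampled at volume onsets. The microtime resolution is
a package choice; 0.1 s makes the discretization error negligible relative to
the TR.

The high-pass filter is implemented as `floor(2T/cutoff)` discrete-cosine
regressors (4 columns at the 128 s cutoff) *inside* the design matrix rather
than as pre-filtering, keeping estimation a single least-squares problem;
condition betas are invariant to adding such columns when the signal is
orthogonal to them, which the test suite checks numerically. Six motion
regressors can be appended; the constant column is last and carries the
baseline, so condition betas are already "relative to fixation".

AR(1) whitening (`fit_glm(..., whiten = TRUE)`) estimates a single pooled
lag-1 coefficient from all voxels' OLS residuals and refits on prewhitened
data. This approximates pooled restricted-ML serial-correlation estimation
with one global coefficient; it is off by default because the package's
calibration runs are noiseless and the estimator is consistent only as run
length grows (at 106 volumes the residual projection visibly shrinks the
estimate, which the tests document). Global proportional scaling is available
but not part of any default path for the same reason.

## Split-half RDMs

For each subject, condition patterns are averaged over odd runs (1, 3) and
even runs (2, 4); `r_ij` is the Pearson correlation across voxels between
odd-half pattern *i* and even-half pattern *j*, and the dissimilarity matrix
is `D = 1 − (r_ij + r_ji)/2`. The raw split-half matrix is asymmetric;
averaging the two split directions is the standard symmetrization and is the
package's documented choice. The diagonal (1 − split-half reliability) is
stored but excluded from every inferential quantity. Entries live in [0, 2];
1 means uncorrelated patterns, 2 perfectly anticorrelated ones.

## Exhaustive ANOSIM over category partitions

`anosim_r()` ranks the 28 off-diagonal dissimilarities (average ranks for
ties — the rank-statistics default) and computes
R = (mean between-category rank − mean within-category rank) / (M/2),
M = 28. The test (`anosim_test()`) evaluates R for *all* labeled assignments
of the 8 conditions to categories of sizes 4/2/2: C(8,4) × C(4,2) = 420
models, with the hypothesized model first. The p-value is the fraction of the
420 null values at or above the hypothesized R, observed model included, so
the smallest attainable p is 1/420.

Because R depends only on the within/between split, swapping the labels of
the two size-2 categories never changes it: the 420 labeled models form 210
structurally distinct pairs, and a partition that strictly beats every
distinct alternative still has its own label-swap twin in the null. The
minimum *achievable* p for a real geometry is therefore 2/420 ≈ 0.00476,
which prints as 0.005 — exactly the floor the exhaustive test exhibits on a
noiseless, strongly clustered cohort. The package keeps the 420-model count
(the natural labeled enumeration) and documents the degeneracy rather than
collapsing to 210.

## Mantel test, group similarity, traits

`mantel_test()` correlates the 28 off-diagonal entries of two RDMs and builds
the null by relabeling the conditions of one matrix: all 8! = 40,320
permutations by default (cheap at n = 8), or a seeded Monte-Carlo sample for
larger problems. The test is one-sided (permuted r ≥ observed) with the
identity included — the convention for "are these matrices similar", chosen
because the direction of the alternative is unambiguous here.

`within_between_similarity()` correlates each subject's RDM with the
leave-one-out mean RDM of their own group and the full mean RDM of the other
group, Fisher-Z transforms both, and runs a two-way ANOVA (correlation type ×
group). With 46 subjects contributing one within- and one between-value each,
the error stratum is genuinely ambiguous in a report of F(1, 44); the package
defaults to the between-cells ANOVA and exposes a subject-stratified mixed
variant, and both partial and generalized eta squared are always emitted
because reports mix the two conventions.

`trait_correlations()` computes Spearman's rho between per-subject ANOSIM R
values and each trait, Bonferroni-corrected with a default family of 16
(8 traits × 2 hemispheres — the family is stated nowhere in the designs this
emulates, so it is an explicit, documented default).

## Three-class decoding

`build_samples()` yields 32 samples (4 runs × 8 conditions) with 16/8/8 class
counts. `decode_subject()` runs leave-one-run-out cross-validation; within
each fold the majority class is subsampled without replacement to the
minority count (6 = 2 samples/run × 3 training runs) in each of `n_bootstrap
= 100` draws, a linear SVM (C = 1, one-vs-one, no feature scaling — betas
share a scale within subject) is trained per draw, and accuracy is averaged
over draws and folds. Averaging (rather than majority voting) across draws is
the package's pinned aggregation rule. Chance is 1/3; on pure-noise subjects
mean accuracy calibrates to 33.3%, and the permutation variant re-runs the
whole procedure under each of the 420 relabelings with shared bootstrap
seeds, so models differ only in their labels.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence battery at 100 random fixtures per
statistic, decoding calibration at 50 pure-noise subjects × 30 voxels × 100
bootstraps, the end-to-end zero-noise identifiability chain at 6 subjects ×
33 voxels (one 8-mm sphere at 2-mm isotropic resolution), and the
separation-recovery grid at 5 separation levels × 30 subjects — sizes chosen
so the full suite completes in about a minute while every claim is exercised
at non-trivial scale. The permutation decoding test uses a reduced bootstrap
count (1–2 draws per fold), since the 420-model enumeration — never reduced —
dominates its cost.

Numerical conventions worth knowing: sphere membership is decided by voxel
*centers* within the radius, inclusive (edge handling is not standardized
elsewhere; an 8-mm sphere on a 2-mm grid centered on a voxel center contains
33 voxels); framewise displacement converts rotations with a 50 mm head
radius; Cohen's d uses the pooled-SD formula, which reproduces printed
demographic tables from their summary statistics; MDS is a metric SMACOF
stress-majorization with a classical-scaling start plus seeded random
restarts, used for visualization only; zero-variance patterns, constant
traits and empty ROIs raise informative errors rather than propagating NaN.

## Limitations

Single-subject ANOSIM R at realistic noise is a noisy quantity; group-level
conclusions should rest on the group-mean RDM (the default) or the full
subject distribution. The AR(1) approximation uses one pooled coefficient,
not voxel-wise or spatially regularized estimates. The pipeline analyzes one
ROI at a time and has no searchlight or whole-brain mode. None of the
supplementary Bayesian analyses of the designs this package emulates are
implemented.
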