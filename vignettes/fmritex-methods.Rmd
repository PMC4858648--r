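---
title: "Texture-based discrimination of true fMRI activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based discrimination of true fMRI activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmritex)
```

## The problem

Individual (single-subject) fMRI analysis thresholds a statistical map to
separate true functional activity from noise, and the threshold is chosen by
eye. Clusters that survive it are a mixture: activation in anatomically
plausible regions for the task ("expected", E) and activation elsewhere —
false positives or non-essential activity ("non-expected", NE). `fmritex`
implements a radiomic approach to this triage: the spatial heterogeneity of
the *mean echo-planar imaging (EPI) volume* inside each activation cluster
carries information about whether the cluster is truly active, because BOLD
fluctuation between task and rest phases leaves truly active tissue more
heterogeneous in the time-averaged image. The package quantifies that
heterogeneity with gray-level co-occurrence matrix (GLCM) texture features
and classifies clusters with a stepwise logistic model evaluated under
patient-grouped cross-validation.

## Texture model

Each ROI is processed slice by slice along the axial axis. Intensities are
pooled over all in-ROI voxels of the ROI and quantized into `n_levels = 8`
equal-width bins spanning the pooled min–max range (top edge closed).
Quantizing against the per-ROI range — rather than a global volume range —
makes every downstream feature invariant to affine intensity shifts of the
ROI, which matters because EPI intensity units are arbitrary.

For each of the four directions θ ∈ {0°, 45°, 90°, 135°} at unit pixel
offset, co-occurrences of quantized levels are counted over every ordered
in-ROI pixel pair, symmetrically (each pair feeds both (i, j) and (j, i)).
Raw counts are accumulated across the ROI's slices and normalized once, so a
40-pixel slice outweighs a 4-pixel sliver; normalizing per slice and
averaging would weight them equally, which we judged wrong for clusters with
ragged extents. Diagonal offsets use unit index steps with no correction for
anisotropic voxel size. From each normalized GLCM the package computes the
20 classical features (Haralick's set, Soh's additions, Clausi's two
normalized inverse-difference measures; `texture_feature_names`), and the
four directional vectors are averaged into a rotation-invariant vector.
Because a 90° rotation of the pixel grid merely permutes the direction set
under symmetric counting, the averaged vector is exactly rotation invariant
— a property the test suite checks to 1e-9.

Numerical conventions, chosen once and applied everywhere: natural
logarithms in all entropies (base only rescales a feature used relatively);
0·log 0 := 0; sum variance is the variance of the i+j distribution about the
*sum average* (the standard correction of the classical definition);
correlation := 1 when a marginal is degenerate (all mass on the diagonal
implies deterministic equality); the first information measure of
correlation is 0 when max(HX, HY) = 0; the second clamps a slightly negative
radicand to 0. A constant ROI quantizes to all-ones with a degeneracy flag;
a single-pixel ROI has no pairs in any direction and its features are
reported as undefined rather than silently zero.

## Labeling

Cluster class labels come from an anatomical cluster report (region, voxel
count, maximum Z per region — the format of an xjView summary). The default
vocabulary assigns language-eloquent regions (Brodmann 44/45/22, inferior
and middle frontal gyri, superior temporal gyrus) to E and common
non-task-related sites (cerebellum, sub-gyral white matter, insula,
postcentral, supramarginal, superior frontal gyri) to NE; the lists are
configurable because no fixed vocabulary is exhaustive. Clusters under
5 voxels are filtered out. A cluster spanning both classes takes the class
of its highest-Z region; an exact cross-class Z tie is refused and flagged
for manual review rather than broken arbitrarily. Two fixed-geometry control
ROIs per subject (5×5×1 voxels at grid positions shared by all subjects) are
labeled NE as ground-truth inactive tissue.

## Statistics and model

Univariate comparisons use the pooled-variance two-sample Student t-test,
two-sided, df = n_E + n_NE − 2, reported uncorrected across the 20 features
(`ttest_pooled`, and `ttest_from_summary` to re-test printed group
summaries). Power curves use the exact noncentral-t formulation with the
per-group sample size as the abscissa; at the strongest feature's effect
size (standardized difference ≈ 0.65) power reaches ~0.9 at 50 per group and
exceeds 0.99 at 100 per group, which is why we read "sample size" on a power
plot as per-group.

The classifier is a forward stepwise binary logistic regression (E = 1) with
a linear logit, features on their raw scale. Entry: among candidates whose
term test gives p < 0.05, add the smallest (ties break lexicographically for
reproducibility). Removal: drop included terms with p > 0.15, largest first.
Guard: an addition whose post-fit AIC exceeds the current model's is
refused, terminating selection. Term tests are Wald by default, matching the
per-term z-and-p presentation typical of regression tables; a
likelihood-ratio entry test is available (`entry_test = "lr"`). One
deliberate robustness choice: under perfect or quasi-perfect separation the
Wald statistic collapses toward zero (the Hauck–Donner effect) and would
both block a perfectly discriminating feature at entry and eject it at
removal, so whenever a fit flags separation the package substitutes the
likelihood-ratio test for that term. Selection is deterministic given the
table.

A null-behaviour fact worth knowing: with 20 independent uninformative
candidates tested at p-enter 0.05, the chance that *no* feature enters is
0.95²⁰ ≈ 0.36, and the AIC guard does not change this (a Wald/LR p below
0.05 implies a likelihood-ratio statistic above 3.84 > 2, so AIC drops).
Non-empty selections on pure noise in roughly two-thirds of datasets are the
expected behaviour of p-based forward selection, not a defect; this is why
selected-feature lists from small studies should be read with the
cross-validated performance, not on their own.

## Evaluation

Evaluation is repeated holdout grouped by subject: 12 of 15 subjects train,
3 test, 100 independent uniformly random partitions (sampling with
replacement across repeats; with C(15,3) = 455 partitions some recurrence is
expected). Grouping by subject prevents a patient's intrinsic texture
character from leaking between training and test. Stepwise selection is
re-run inside every training fold. Reported metrics per repeat: accuracy at
probability threshold 0.5 ("success rate" — the threshold is our choice, as
none is standard), trapezoidal AUC (equal to the tie-corrected normalized
Mann–Whitney U statistic, which the tests assert exactly), and the
sensitivity/specificity of the Youden-optimal point (J = sens + spec − 1;
again our choice of optimality criterion). Aggregates are arithmetic means
over repeats; a repeat whose test subjects happen to contain one class has
undefined AUC and is excluded from those means with a warning.

## Synthetic data: what it emulates and what it does not

No human scans ship with the package; two generators make every stage
testable.

**Feature-table generator** (`generate_feature_table`): draws 43 E and 73 NE
rows from per-class multivariate Gaussians whose per-feature means and SDs
default to the study population's printed values
(`default_feature_params()`), with a 0.99 equicorrelation block among the
four intensity-scale features (autocorrelation, sum of squares variance, sum
average, sum variance) that are near-collinear in this kind of data. Two
features (the normalized inverse-difference pair) are nearly constant with
SDs below print resolution; their SDs are floored at 0.02 so generated
designs have full rank. Subject ids are assigned round-robin over 15
subjects so grouped splitting is exercised. Joint Gaussianity is an explicit
simplification — real radiomic features are skewed, bounded and nonlinearly
dependent — so cross-validated metrics from these tables approximate, but
cannot match, results on real data whose full covariance is unknown. Under
the defaults the grouped-CV AUC lands in the low-to-mid 0.7s, the right
qualitative vicinity of the ~0.8 reported on real data.

**Volume generator** (`generate_volume_dataset`): per subject, a 64×64×30
background of smoothed Gaussian noise; 43 E plus 43 NE activation boxes
(9×9×3 voxels) across the cohort, each filled with a Gaussian random field
realized by convolving white noise with an isotropic Gaussian kernel of the
class's correlation length — E rough (0.6 voxels), NE smooth (2.0 voxels),
encoding the finding that truly active tissue is the more heterogeneous
class; plus the two fixed control ROIs per subject sampling the smooth
background, for 116 ROIs at 37%/63% prevalence. All fields pass through a
monotone log-normal transform (shape 0.75) giving the right-skewed marginals
typical of EPI magnitude images; with a right-skewed marginal, a rough ROI
samples the upper tail more fully, stretching its quantization range upward
and lowering its mean quantized level, so the smooth NE class scores higher
on sum average as well as on autocorrelation and homogeneity — the observed
direction of the class effect. The monotone transform is applied after
smoothing, so it preserves the between-class smoothness ordering. The
generator is idealized: its two classes differ by construction in exactly
one mechanism (correlation length), there is no anatomy, no partial-volume
mixing, no physiological noise, and the resulting classes are far more
separable than real E/NE clusters (cross-validated AUC saturates near 1.0).
Passing end-to-end tests on it demonstrates the pipeline's mechanics and the
direction of the texture effect, not field performance; the feature-table
generator is the calibrated benchmark for headline metrics. Setting both
correlation lengths (nearly) equal removes the class contrast entirely and
drives grouped-CV AUC to 0.5, an end-to-end null check in the tests.

## Problem sizes and defaults

Defaults mirror the study design throughout: 8 gray levels, pair distance 1,
p-enter 0.05 / p-remove 0.15, 12-of-15 training subjects, 100 CV repeats,
116 ROIs at 43/73. The test suite uses these sizes where the property under
test needs them (oracle equivalence on 200 random patches, rotation
invariance on 100, stepwise recovery on 200 replicates of 116×20 tables, 100
split plans) and reduced cohorts (6–8 subjects, 40×40×12 volumes) where only
the mechanics are exercised. The acceptance script
(`scripts/acceptance.R`) re-runs the full-size table-level evaluation and
the full-size image-level cohort.

## Known limitations

- The GLCM is 2-D per slice; 3-D (26-neighbour) co-occurrence, other
  radiomic families and IBSI certification are out of scope.
- Whether to compute texture slice-wise or on one representative slice is
  not settled in this application; we accumulate counts over all slices and
  document it as a choice.
- Wald-based stepping and raw-scale features reproduce the original
  analysis style; neither is the statistically optimal modern choice
  (penalized likelihood would handle separation and collinearity more
  gracefully).
- The 0.99-correlated feature block makes coefficient values of the four
  intensity-scale features individually unstable in any logistic model that
  includes more than one of them; selected-feature identity, not
  coefficient magnitude, is the stable output.
- Masks are assumed to share the mean volume's grid; no resampling is
  performed.
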