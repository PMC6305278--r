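---
title: "Radiomic texture analysis of prostate mpMRI: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic texture analysis of prostate mpMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsradiomics)
```

## The problem

Gleason score (GS), the histopathological grade of prostate cancer, drives
clinical management, but obtaining it requires biopsy. Radiomics asks
whether quantitative texture statistics computed from routine
multi-parametric MRI (T2-weighted imaging plus the apparent diffusion
coefficient map derived from diffusion-weighted imaging) carry enough
information to discriminate GS groups non-invasively. `gsradiomics`
implements that analysis end to end: for each patient a lesion-centred
sub-volume is cut from both modalities, quantized, and encoded into 41
features; features are screened one at a time for association with the GS
group; and a one-vs-rest random-forest classifier quantifies multivariate
predictive performance and ranks features by out-of-bag permutation
importance.

The GS groups follow the clinical three-tier scheme: group 1 for GS \(\le\) 6,
group 2 for GS 3+4, group 3 for primary pattern 4 or higher (4+3, 8, 9, 10).
A five-tier Gleason Grade Group mode (`scheme = "five"`) is available for
re-analyses at a finer grading resolution.

## Region of interest and quantization

Each lesion contributes one sub-volume of **21 × 21 × 3 voxels** centred on
the lesion centroid, extracted independently in each modality's own voxel
grid (no inter-modality registration or resampling is attempted; the two
windows therefore cover different physical extents when in-plane
resolutions differ, which is a deliberate, literal per-image reading).
Windows that would cross a volume boundary are shifted by the minimal
amount needed to fit, with a warning, rather than padded — zero-padding
would inject an artificial homogeneous zone into the size-zone statistics.

Intensities are uniformly quantized to **Ng = 32 gray levels** over the
patch's own min–max range:
\(\ell(v) = \min\{N_g, \lfloor (v - v_{\min})/(v_{\max} - v_{\min}) \cdot N_g\rfloor + 1\}\).
Patch-local binning (rather than volume-global) makes every downstream
feature invariant to affine intensity transforms of the patch, i.e. to
scanner gain and offset; it also makes the result independent of whether
whole-volume normalization (`normalize_volume()`, min–max by default,
z-score as an option) was applied first. A constant patch maps to level 1
throughout, so the degenerate formulas below stay defined.

## The 41 features

The canonical feature vector is 6 histogram + 19 GLCM + 5 NGTDM + 11 GLSZM
statistics, in fixed order (`feature_names()`).

**Histogram (6).** Mean, variance, skewness, kurtosis (excess), energy
\(\sum_k h(k)^2\) and entropy \(-\sum_k h(k)\log_2 h(k)\) of the quantized
level histogram. A zero-variance patch has skewness and kurtosis defined as
0. Computing these on quantized levels keeps them commensurate across
scanners and consistent with the single quantization step of the pipeline.

**GLCM (19).** The co-occurrence matrix \(P(i,j)\) pools pair counts over
the 13 unique 3D direction offsets at chessboard distance 1, counted in
both orders (symmetric, the standard Haralick convention), then normalizes
once. Pooling before normalization (rather than averaging features per
direction) was chosen for simplicity and rotation robustness; an axial
4-direction mode and custom offsets are available
(`compute_glcm(directions = )`). The 19 features are the Haralick/Soh set
listed in `glcm_features()`; all entropies use base-2 logarithms with
zero-probability terms contributing 0, and the correlation of a
zero-variance matrix is defined as 0. Sum variance is computed about the
sum average.

**NGTDM (5).** Following the original Amadasun convention, only voxels with
a complete 26-neighborhood contribute — for a 3-slice patch, the interior
of the middle slice. Coarseness is \(1/(\varepsilon + \sum_i p_i s_i)\)
with \(\varepsilon = 10^{-6}\) (configurable); the original reference
leaves the guard open, and this cap makes the constant-patch coarseness
exactly \(10^6\) instead of infinite.

**GLSZM (11).** Zones are maximal **26-connected** components of equal gray
level (the most permissive standard choice; 6-connectivity is a config
option). Every voxel belongs to exactly one zone, an invariant the test
suite checks against an independent flood-fill oracle. Zone size
percentage, \(N_z/N_v\), is the zone count per voxel: 1 when every voxel is
its own zone, small when a few large homogeneous zones dominate — which is
why it rises with lesion fragmentation while large-zone-size emphasis
falls.

**Modality averaging.** Features are extracted separately from the T2 and
ADC patches and averaged elementwise (`mode = "mean"`); single-modality
vectors are available for per-modality re-analysis.

**Cohort scaling.** `scale_features()` min–max rescales each feature column
to [0, 1] over the cohort. The rank-based screen is invariant to it, and
random forests are invariant to monotone per-feature transforms, so it is
cosmetic for the analyses here; it is kept because summary tables on the
unit scale are easier to compare across features. In the hold-out
experiment scaling parameters are computed on the training subset only and
applied, without clipping, to the test subset, to avoid leakage.

## Univariate screen

Per feature, a Kruskal-Wallis test (tie-corrected, chi-square
approximation) compares the groups, and Spearman's rank correlation
(average ranks for the heavily tied group labels, large-sample t
approximation) measures monotone association with the ordinal group index.
Each family of 41 p-values is Holm-Bonferroni corrected **separately**,
mirroring two independent analyses; a pooled 82-test family is available
via `single_family = TRUE`. Degenerate inputs (constant feature, single
group) return \(H = 0, p = 1\) or \(\rho = 0, p = 1\) with a warning
instead of failing, so one pathological column cannot abort a screen.
Group summaries report median and IQR (Q3 − Q1, linear-interpolation
quantiles; the quantile convention is not standardized in the field, so it
is stated here).

## Classification

Each group is classified one-vs-rest with a random forest of **500 trees**
(sqrt-feature subsampling, unlimited depth, bootstrap on — canonical
defaults, all exposed in `rf_config()`), evaluated by **stratified 5-fold
cross-validation**. Stratification is a deliberate strengthening of plain
equal-sized folds: with ~30 positives per task, unstratified folds can
lose a class entirely. AUC is the Mann-Whitney probability (ties counted
half); accuracy, NPV and PPV come from hard predictions at threshold 0.5
(the threshold is a convention, not tuned). Metrics are averaged over
folds; out-of-fold predictions are also pooled into one confusion matrix.

A balanced hold-out run (`holdout_rf()`) draws 40 training and 20 test
patients, half positive each, fits once and evaluates once; patients not
drawn are left unused and counted, replicating the small-cohort validation
design literally.

**Permutation importance.** For every tree, the increase in out-of-bag
error after permuting one feature among that tree's out-of-bag samples is
recorded; per forest the mean over trees is divided by the standard
deviation of the per-tree increases, and the normalized values are averaged
across the 5 folds. "Divide by the ensemble's standard deviation" admits
another reading (SD of the OOB errors themselves); the per-tree-SD reading
is used because it makes the score a signal-to-noise ratio with a natural
null scale around zero. Under label permutation this estimator shows a
small negative bias — permuting a useless feature occasionally *improves*
out-of-bag predictions — so "no predictive value" should be read as
"importance near or below zero", not exactly zero.

**Seeding.** All randomness (fold assignment, per-fold forest fits,
hold-out draws, cohort generation) derives from one master seed by a fixed
stream-splitting rule: the master seed seeds R's RNG, one `sample.int()`
draw per consumer yields child seeds. Any result is replayable from the
configuration alone, and `run_pipeline()` reruns are byte-identical.

## The synthetic cohort generator

Because clinical imaging archives cannot be bundled with a package, it
ships a phantom generator whose *statistical
structure* matches what the analysis assumes: three groups whose lesions
differ in zone-size texture. Each lesion texture is a random packing of
homogeneous spherical blobs — intensity drawn uniformly on [0, 1] per blob
— over a constant background, plus Gaussian noise. The mean blob diameter
is the group's dial: **9 / 5 / 2 voxels** for groups 1/2/3 by default, so
group 1 lesions are a few large homogeneous zones and group 3 lesions many
small fragmented ones. A blob-placement model was chosen over, say,
Gaussian random fields because it manipulates directly the zone-size
distribution that GLSZM measures, making the expected sign pattern
(large-zone-size emphasis falling, zone-size percentage rising with group)
a designed property rather than an accident.

Defaults, chosen once: 30 patients per group; 64 × 64 × 19 voxel volumes (a
scaled stand-in for a 320 × 320 × 19 clinical acquisition, keeping
simulation fast; configurable); lesion half-width 12 voxels, so the
21 × 21 × 3 ROI sits fully inside the textured box; background level 0.35;
noise SD 0.02 of the unit signal range — large enough to occupy many of the
32 gray levels, small enough not to shatter the designed zones. Blob
intensities have the same distribution in every group, so intensity
histograms alone are uninformative by construction, and T2 and ADC
textures are *independent* draws with the same group parameters, since the
analysis averages features across modalities and assumes nothing about
inter-modality correlation. Setting the three blob scales equal gives an
exchangeable null cohort, used for calibration testing.

**What the phantom does not emulate** — and hence what passing tests do and
do not show: no prostate anatomy, no partial-volume or bias-field effects,
no inter-modality spatial correlation, no overlap between groups' texture
distributions beyond what noise induces. The group separation is therefore
far stronger than in clinical data: on the default cohort the screen's
significant correlations reach |ρ| ≈ 0.94 and the classifiers are at or
near AUC 100%, where clinical cohorts sit near moderate correlations and
AUC 70–85%. The synthetic results validate the *machinery* (signs,
calibration, determinism), not clinical effect sizes.

## Numerical and degenerate-case conventions

* Quantization: constant patch → all level 1; normalization: constant
  volume → all zeros.
* GLCM: zero-variance correlation → 0; information correlation 2 clamped
  at 0 before the square root.
* NGTDM: single-occupied-level patch → contrast, busyness, complexity,
  strength all 0.
* Kruskal-Wallis / Spearman degenerate input → (0, 1) with a warning.
* NPV/PPV with an empty denominator are NA within a fold and excluded from
  the fold average.
* ROI boundary handling: minimal shift plus warning, never padding, never a
  dropped patient.

## Problem sizes used by the test suite

The suite validates the texture matrices against brute-force oracles on
20 random patches up to 7 × 7 × 3 at up to 4 gray levels (exact equality
for counts, 1e−10 for probabilities); recovers the zone-size sign pattern
on a seeded 30/30/30 cohort with blob scales 9/5/2; and calibrates the
screen on 200 exchangeable-null replicates of 30 patients built from
12 × 12 × 3 lesion patches — a patch size chosen to keep the calibration
loop proportionate while leaving all 41 features well defined. The
label-permuted classifier null uses 20 cross-validation replicates at the
full 500 trees.

## Known limitations

* No DICOM ingestion, bias-field correction, registration, or resampling;
  volumes are consumed as-is in NIfTI form.
* The 21 × 21 window is defined in each image's own voxel units; when T2
  and ADC resolutions differ, the physical extents differ too.
* Shape and filtered (wavelet/Laplacian-of-Gaussian) features, run-length
  matrices, and alternative classifiers are out of scope.
* Whether published summary tables in this field reflect cohort-level
  scaling or raw feature values is often unstated; `scale_features()` is
  on by default and toggleable, and the rank-based screen is unaffected
  either way.
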