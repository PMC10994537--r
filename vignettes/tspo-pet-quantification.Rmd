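---
title: "Reference-free TSPO-PET quantification and outcome statistics: models, parameters and design choices"
author: "tspopet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free TSPO-PET quantification and outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspopet)
```

## The problem

TSPO radioligand binding indexes microglial activation, but TSPO is
expressed brain-wide, so there is no anatomical region that can serve as a
classical reference for the simplified reference tissue model. The package
implements the standard supervised-cluster escape from this circularity:
learn what "low specific binding grey matter" kinetics look like from
control subjects, find the voxels in each individual that behave that way,
and use their average raw time-activity curve as that subject's
pseudo-reference. Binding-potential maps then follow from SRTM2, and group
and outcome statistics operate on those maps.

## Models

### Kinetics

All kinetic quantities use minutes. The quantification rests on the SRTM
operational equation

$$C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_{2a})\,\big[C_R \otimes e^{-k_{2a}t}\big](t)$$

with $R_1$ the target-to-reference delivery ratio, $k_2$ the target efflux
rate, $k_{2a}$ the apparent efflux rate, and the non-displaceable binding
potential $BP_{ND} = k_2/k_{2a} - 1$. The reference efflux rate is
$k_2' = k_2/R_1$. The same equation is used in both directions: as the
forward model in the synthetic phantoms and as the fitting model.

Fitting is by basis functions. For each candidate $k_{2a}$ on a grid, the
convolution term is precomputed on a 1-s uniform grid and averaged over the
acquisition frames, turning the fit per candidate into ordinary least
squares — two coefficients for the first SRTM pass, one ($R_1$) for the
SRTM2 pass once $k_2'$ is fixed. The candidate with the smallest residual
wins.

### The four-step pipeline

1. **Per-frame normalization.** Every frame is z-scored within the brain
   mask (population SD; see *Numerical choices*). Class construction and
   unmixing operate on normalized curves so that subjects and frames are
   comparable; kinetic fitting operates on raw activity.
2. **SVCA classes** per affinity group (HAB and MAB separately, since the
   rs6971 genotype changes the binding affinity): blood = the 40 voxels
   with the largest duration-weighted activity over frames ending within
   the first 180 s; specific-binding GM = eroded thalamus; non-specific GM
   = eroded cerebellar GM; white matter = eroded WM. Per-subject curves are
   averaged over retained controls.
3. **NNLS unmixing.** Each in-mask voxel's normalized TAC is decomposed
   onto the four class curves under non-negativity (Lawson–Hanson). The
   low-binding weight ratio — the non-specific-GM weight over the sum of
   all four weights — is thresholded at 0.9 to define the pseudo-reference
   voxels; the reference TAC is the mean *raw* curve over them.
4. **SRTM2 maps.** A first SRTM pass over all brain voxels yields per-voxel
   $k_2'$; the median over voxels with $BP_{ND} > 0.1$ becomes the global
   $k_2'$, and the one-parameter SRTM2 refit produces the $BP_{ND}$, $R_1$
   and $k_{2a}$ maps.

### Statistics

Voxel-wise group contrasts use pooled-variance two-tailed t-tests with
Benjamini–Hochberg adjustment across in-mask voxels; the signed z map
$z = \mathrm{sign}(t)\,\Phi^{-1}(1-p/2)$ is zeroed where the adjusted p
exceeds 0.05, and Cohen's d maps are classified moderate/large/very large
at 0.8 and 1.2. VOI analyses use a group × VOI two-way ANOVA with the TSPO
genotype as an additive covariate and type-II sums of squares, Tukey-HSD
post hocs (the within-VOI pairwise comparisons are taken from the
group-by-VOI cell-mean family, so they inherit the full family's
multiplicity adjustment), Spearman correlations with exact permutation
p-values for n ≤ 9, and Shapiro–Wilk-gated routing between ANOVA and
Kruskal–Wallis for descriptives. The outcome model is NIPALS PLS1 of CRS-R
on all in-mask voxels, with VIP scores
$\mathrm{VIP}_j = \sqrt{p\,\sum_a \mathrm{SSY}_a (w_{ja}/\lVert w_a\rVert)^2 / \sum_a \mathrm{SSY}_a}$
reshaped into 3D maps, and leave-one-out cross-validated predictions with
the component count chosen per fold by an inner leave-one-out RMSE
criterion.

## The synthetic cohort generator

The generator is the package's ground truth and defines the conditions
under which everything is validated.

* **Geometry.** 32 × 32 × 16 voxels at 4 mm isotropic, with the 17 named
  regions of the analysis (13 hypothesis VOIs, the precentral control
  region, cerebellar GM, white matter, a blood pool) laid out as disjoint
  cuboids of 216 voxels each — large enough for voxel-wise statistics and
  erosion, small enough that a full pipeline run takes seconds.
* **Acquisition.** The 60-min, 32-frame schedule (six 10-s, eight 30-s,
  five 1-min, five 2-min, eight 5-min frames). Simulation runs on a 1-s
  grid with trapezoidal frame averaging.
* **Kinetics.** A Feng tri-exponential bolus drives a one-tissue reference
  compartment ($K_1 = 0.1\,\mathrm{min}^{-1}$, $k_2' = 0.05\,
  \mathrm{min}^{-1}$); each tissue region follows the SRTM forward model
  with delivery $R_1 \in [0.8, 1.2]$ and baseline binding 0.2–1.0
  (thalamus highest at 1.0). These are plausible synthetic values chosen
  once, not estimates from any dataset. The cerebellar GM is given
  $BP_{ND} = 0$ exactly: the pipeline's pseudo-reference search assumes
  such tissue exists, and making it exactly true renders parameter
  recovery identifiable, so recovery error measures the pipeline rather
  than a confounded reference. The blood pool carries the scaled input
  function.
* **Noise.** Gaussian with the standard frame-variance proxy
  $\sigma_f \propto \sqrt{\bar A_f / \Delta t_f}$. The default scale 0.3
  gives early bolus frames with CV above 100 % and 5-min frames near 2 %,
  i.e. voxel-level noise in the range seen in dynamic PET. What the
  generator does **not** emulate: scanner PSF and partial-volume effects,
  attenuation/scatter residuals, motion, anatomical variability, lesion
  morphology. Passing recovery tests therefore validates the estimators
  and their numerics, not robustness to those artefacts.
* **Cohort structure.** Default composition 24 controls / 6 anoxic / 11
  traumatic. Anoxic subjects receive uniform BP increments of 0.5–1.0 in
  thalamus, pallidum, putamen, PCC, mPFC, precuneus and cuneus; traumatic
  subjects in mPFC only; the precentral control region is never
  incremented. CRS-R is a rounded noisy decreasing logistic function of
  pallidal binding mapped onto 0–23 (centre 0.8, scale 0.25, noise SD 2
  points); scores below 8 are labelled VS/UWS or (with probability 0.25)
  deceased with CRS-R recoded to 0, 8–17 MCS, 18+ EMCS; the binarized
  outcome is favourable iff MCS/EMCS. A configurable fraction of
  low-affinity binders is generated with an exclusion flag (default 0,
  matching an enrolled cohort after genotype screening). Effect sizes are
  free parameters of the generator — no quantitative regional effect sizes
  exist to copy — so validation is parameter recovery and
  detection/specificity, not value matching.

## Numerical choices

* **Normalization SD.** Population (divide-by-n) SD, fixed for
  reproducibility; whether real pipelines use n or n−1 is immaterial to
  any downstream quantity except by a constant frame factor, which the
  NNLS weights absorb.
* **Erosion.** 6-connectivity (face neighbours), one iteration by default;
  grid borders count as background.
* **Blood window aggregation.** "Most activity within the first 3 min" is
  operationalized as the duration-weighted sum over frames that end within
  180 s, with lexicographic tie-breaking for determinism.
* **Outlier rule for class creation.** A control is excluded when the RMS
  deviation of its non-specific-GM curve from the leave-one-out group mean
  exceeds 3 × the group median of those deviations — deterministic,
  scale-free, and reproduces a 1-of-N exclusion on a constructed outlier.
* **Reference curve units.** The reference TAC averages raw activity, not
  z-scores: reference-tissue kinetic modelling is dimensionally meaningful
  only in activity units. The normalized image is used only to locate the
  reference voxels.
* **Basis grid.** 256 log-spaced $k_{2a}$ values on [0.006, 0.6] min⁻¹,
  bracketing plausible human TSPO kinetics. After the grid search the
  residual profile is interpolated parabolically in $\log k_{2a}$ between
  the two neighbouring grid points and the exact regressor rebuilt at the
  refined value, accepted only if the residual decreases; this removes the
  ~±1 % binding quantization of a 256-point grid while preserving the grid
  solution as an upper bound.
* **Reference curve reconstruction.** Fitting needs the reference on the
  fine grid, but a measured TAC contains frame *averages*, not samples.
  The package interpolates through (0, 0) and the frame mid-times, then
  iteratively adjusts the knot values until the interpolant's frame
  averages reproduce the measured values. Without this correction the
  bolus frames are systematically distorted and regional binding acquires
  a bias of several percent.
* **Global efflux pooling.** Median of per-voxel $k_2'$ over voxels with
  first-pass $BP_{ND} > 0.1$; near-zero-binding voxels carry almost no
  information about $k_2'$, and the median resists the heavy tails of
  voxel-wise first-pass fits.
* **Negative binding.** Negative $BP_{ND}$ estimates are retained by
  default so group statistics remain unbiased; clipping is available
  behind a flag.
* **Degenerate inputs.** Constant frames, empty masks, all-zero reference
  curves, constant correlation inputs and single-level factors raise
  informative errors rather than propagating NaN.

## Design decisions that were genuinely open

* **Welch vs pooled t.** Pooled variance, matching "Student's" tests;
  Welch sits behind a flag.
* **z-map sign.** Positive z means higher mean in the first-listed group.
* **ANOVA covariate.** Genotype enters as an additive fixed factor
  (ANCOVA-style); with a single genotype level it is dropped
  automatically.
* **PLS target.** Continuous CRS-R at follow-up, with deceased subjects
  entering at CRS-R = 0; predictors are centred but not variance-scaled
  (binding maps share units), and scaling is a flag because VIP values
  depend on it. VIP "importance" uses the strict > 1 convention.
* **Blood-voxel selection scope.** Per subject, since the normalized
  curves are subject-specific.
* **Spearman p-values.** Own implementation: exact enumeration for n ≤ 9
  with mid-rank ties, t-approximation beyond; the stats package serves as
  an independent cross-check in the tests.

## Problem sizes used in validation

The test-suite and acceptance-script simulations use the default
32 × 32 × 16 phantom for pipeline recovery (3 672 brain voxels, 216 per
region), a 16 × 16 × 8 variant (170 brain voxels) for the 200-replicate
null-cohort FDR calibration, 100 replicate cohorts at the VOI level for
detection/specificity, and 100 random four-class problems for the NNLS
oracle comparison. These sizes were chosen so a full validation run
completes in minutes while keeping every region at or above 100 voxels
where voxel-averaging behaviour matters.

## Known limitations

* The phantom's homogeneous cuboid regions make NNLS class separation
  easier than in real anatomy; partial-volume mixing at region borders is
  not represented (erosion is exercised mechanically, not as a true
  partial-volume control).
* The pseudo-reference assumption is made exactly true in the generator;
  in real data low-binding grey matter retains some specific binding and
  $BP_{ND}$ is correspondingly compressed.
* Registration, motion and segmentation are out of scope; images are
  assumed voxel-aligned to the label map.
* The first-pass SRTM runs on the same basis grid as SRTM2 without the
  parabolic refinement; the median pooling across voxels makes the global
  $k_2'$ insensitive to the residual quantization.
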