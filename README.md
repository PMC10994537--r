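# tspopet

Quantification of neuroimmune activation from dynamic TSPO-PET, without
arterial blood sampling, plus the group- and outcome-level statistics used
to relate regional binding to clinical recovery after severe brain injury.

The 18-kDa translocator protein (TSPO) is overexpressed by activated
microglia, so the binding of TSPO radioligands such as ¹⁸F-DPA-714 is an
*in vivo* readout of neuroinflammation. Because TSPO is expressed throughout
the brain, no anatomical region can be assumed devoid of specific binding
and a conventional reference region does not exist. This package implements
the supervised-cluster workaround and everything downstream of it:

1. **SVCA class curves** — per binding-affinity genotype group (HAB/MAB),
   four normalized kinetic class curves are built from control subjects:
   typical blood (the 40 early-hottest voxels), specific-binding grey
   matter (eroded thalamus), non-specific-binding grey matter (eroded
   cerebellar grey matter) and white matter. Controls with an outlying
   non-specific profile are excluded.
2. **NNLS unmixing** — every brain voxel's frame-normalized time-activity
   curve (TAC) is decomposed as a non-negative combination of the four
   classes; voxels whose non-specific-GM weight ratio exceeds 0.9 form the
   subject's *ad hoc* pseudo-reference region, whose raw mean TAC is the
   reference curve.
3. **SRTM2 parametric maps** — the simplified reference tissue model

   `C_T(t) = R1·C_R(t) + (k2 − R1·k2a)·[C_R ⊗ e^(−k2a·t)](t)`

   is fitted voxel-wise with basis functions. A first SRTM pass estimates
   the reference efflux rate k2′ = k2/R1, which is then fixed globally
   (SRTM2) and each voxel refit for R1 and k2a, giving the binding
   potential map `BP_ND = R1·k2′/k2a − 1` (the "TSPO level").
4. **Statistics** — voxel-wise two-sample t maps with Benjamini–Hochberg
   FDR control, thresholded signed z maps and Cohen's-d effect-size maps;
   volume-of-interest (VOI) two-way ANOVA (group × VOI, genotype covariate,
   type-II sums of squares) with Tukey-HSD post hocs; Spearman correlations
   between regional binding and the 23-point Coma Recovery Scale-Revised
   (CRS-R); and a whole-brain PLS regression of outcome on voxel-wise
   binding with variable-importance-in-projection (VIP) maps and
   leave-one-out cross-validated predictions.

Because real patient images cannot be redistributed, the package ships a
**synthetic dynamic-PET cohort generator** with known ground truth: digital
phantoms whose regional kinetics follow the forward SRTM model driven by a
Feng-type input function, cohort composition matching the study design
(24 controls, 6 anoxic, 11 traumatic), anoxic binding elevations in
mesocircuit/posteromedial regions, traumatic elevations in medial
prefrontal cortex, and CRS-R outcomes linked negatively to pallidal
binding. Every pipeline stage is validated by parameter recovery against
this generator.

## Worked example

```r
library(tspopet)

sched <- dpa_frame_schedule()
sched
#> <frame_schedule> 32 frames, 3600 s total (60.0 min)

# a noisy phantom subject plus three controls for class creation
ph <- build_phantom(phantom_spec(noise_scale = 0.3, seed = 42))
controls <- lapply(1:3, function(i)
  build_phantom(phantom_spec(noise_scale = 0.3, seed = 100 + i))$image)

classes <- build_class_set(controls, ph$labels, ph$brain_mask, "HAB")
classes
#> <kinetic_class_set> HAB, 32 frames, built from 3 controls

fit <- quantify_subject(ph$image, classes, ph$brain_mask)
fit$map
#> <parametric_map> 3672 fitted voxels, k2p_global = 0.0500 /min, bp range [-0.41, 1.09]

est <- sapply(c("thalamus", "globus_pallidum", "precentral"), function(r)
  mean(fit$map$bp[region_mask(ph$labels, r)]))
round(data.frame(estimated = est,
                 true = ph$truth$bp[match(names(est), ph$truth$region)]), 3)
#>                 estimated true
#> thalamus            1.003 1.00
#> globus_pallidum     0.504 0.50
#> precentral          0.252 0.25
```

The global efflux rate is recovered at its simulated value (0.05 min⁻¹)
and regional binding potentials are recovered to well under a percent at
this noise level. From `fit$map` onward, `voi_table()`, `two_way_anova()`,
`tukey_hsd()`, `voxelwise_ttest()`, `spearman_cor()` and
`pls1_fit()`/`vip_scores()`/`loo_predict()` provide the group and outcome
analyses; `simulate_cohort()` generates whole cohorts with records,
genotypes and CRS-R outcomes.

A thin command-line wrapper for the file-based workflow (NIfTI images with
JSON frame-schedule sidecars) lives at `inst/cli/tspopet.R`:

```sh
Rscript inst/cli/tspopet.R simulate-cohort --out cohort/ --seed 1 --images
Rscript inst/cli/tspopet.R build-classes --subjects cohort/subjects.tsv \
    --images cohort/ --labels cohort/labels.nii.gz --affinity HAB \
    --out classes.json
```

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "tspopet",
                               load_package = "installed")'
```

The suite contains per-module unit tests against independent oracles
(exhaustive-support NNLS, ODE solvers, closed-form ANOVA/Tukey/Spearman
computations, brute-force lattice enumeration) plus property-style
invariant checks, and an end-to-end acceptance file exercising parameter
recovery, FDR calibration, detection power and VIP localization.

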