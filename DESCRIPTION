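Package: tspopet
Title: Dynamic TSPO-PET Quantification with Supervised Cluster Reference
    Extraction and SRTM2 Parametric Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies neuroimmune activation from dynamic TSPO-PET
    acquisitions without arterial sampling. Builds supervised-cluster-analysis
    (SVCA) kinetic class curves from control subjects, decomposes voxel
    kinetics by non-negative least squares to locate low-binding pseudo-
    reference voxels, fits the simplified reference tissue model with a
    globally fixed efflux rate (SRTM2) to produce voxel-wise binding-potential
    maps, and runs the downstream group and outcome statistics: voxel-wise
    t-maps with Benjamini-Hochberg false-discovery-rate control, z- and
    effect-size maps, volume-of-interest ANOVA with Tukey HSD, Spearman
    outcome correlations, and partial-least-squares outcome regression with
    variable-importance-in-projection maps. Includes a synthetic dynamic-PET
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    pracma,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
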