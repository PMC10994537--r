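#' Effect specification for the synthetic cohort
#'
#' Controls the implanted group differences and the outcome link. Binding
#' increments are drawn uniformly from `[lo, hi]` per subject and region
#' group. The CRS-R outcome of patients is a noisy decreasing logistic
#' function of their pallidal binding, so that higher mesocircuit binding
#' predicts worse recovery.
#'
#' @param anoxic_lo,anoxic_hi uniform range of the BP increment implanted in
#'   the anoxic-elevated regions (thalamus, pallidum, putamen, PCC, mPFC,
#'   precuneus, cuneus)
#' @param traumatic_lo,traumatic_hi BP increment range for traumatic
#'   subjects, applied in the mPFC only
#' @param subject_sd SD of the additive between-subject jitter on regional BP
#' @param crsr_mid,crsr_scale centre and scale of the logistic CRS-R link on
#'   pallidal BP
#' @param crsr_sd SD of the additive CRS-R noise (scale points)
#' @param lab_fraction probability that a subject is a low-affinity binder
#'   (flagged for exclusion from quantification)
#' @param measurement_sd SD of the additive VOI-level measurement noise used
#'   by the image-free fast path
#' @param noise_scale image noise scale forwarded to [add_noise()] when
#'   images are generated
#' @export
cohort_effects <- function(anoxic_lo = 0.5, anoxic_hi = 1.0,
                           traumatic_lo = 0.5, traumatic_hi = 1.0,
                           subject_sd = 0.05,
                           crsr_mid = 0.8, crsr_scale = 0.25, crsr_sd = 2,
                           lab_fraction = 0,
                           measurement_sd = 0.05,
                           noise_scale = 0.3) {
  list(anoxic_lo = anoxic_lo, anoxic_hi = anoxic_hi,
       traumatic_lo = traumatic_lo, traumatic_hi = traumatic_hi,
       subject_sd = subject_sd,
       crsr_mid = crsr_mid, crsr_scale = crsr_scale, crsr_sd = crsr_sd,
       lab_fraction = lab_fraction,
       measurement_sd = measurement_sd,
       noise_scale = noise_scale)
}

#' Regions with implanted anoxic binding elevation
#' @export
anoxic_regions <- function() {
  c("thalamus", "globus_pallidum", "putamen", "PCC", "mPFC",
    "precuneus", "cuneus")
}

#' Regions with implanted traumatic binding elevation
#' @export
traumatic_regions <- function() "mPFC"

#' Simulate a study cohort with known ground truth
#'
#' Generates subject records (group, genotype, CRS-R outcome, outcome state)
#' and per-subject regional binding-potential ground truth; optionally also
#' full dynamic phantom images. Anoxic subjects receive BP increments in the
#' mesocircuit/posteromedial regions, traumatic subjects in the medial
#' prefrontal cortex, and the precentral-gyrus control region is never
#' incremented. Patients' CRS-R values are a noisy decreasing function of
#' pallidal BP; states and the binarized outcome follow the CRS-R (deceased
#' and VS/UWS below the cut, MCS/EMCS above; outcome favourable iff MCS or
#' EMCS). A pure function of its arguments and `seed`.
#'
#' @param n_controls,n_anoxic,n_traumatic group sizes (defaults: the study
#'   composition 24 / 6 / 11)
#' @param effects a [cohort_effects()] list
#' @param seed integer seed
#' @param images if TRUE, build a noisy dynamic phantom per subject (slow);
#'   if FALSE return only records + ground truth
#' @param spec a [phantom_spec()] used for geometry/kinetics
#' @return list with `records` (data.frame), `true_bp` and `measured_bp`
#'   (subjects x regions matrices; measured = true + VOI-level noise),
#'   `regions`, `spec`, and `images`/`labels`/`brain_mask` when
#'   `images = TRUE`
#' @export
simulate_cohort <- function(n_controls = 24, n_anoxic = 6, n_traumatic = 11,
                            effects = cohort_effects(), seed = 1L,
                            images = FALSE, spec = phantom_spec()) {
  stopifnot(n_controls >= 0, n_anoxic >= 0, n_traumatic >= 0)
  set.seed(as.integer(seed))
  n <- n_controls + n_anoxic + n_traumatic
  group <- factor(rep(c("control", "anoxic", "traumatic"),
                      c(n_controls, n_anoxic, n_traumatic)),
                  levels = c("control", "anoxic", "traumatic"))
  id <- sprintf("S%02d", seq_len(n))
  genotype <- ifelse(stats::runif(n) < effects$lab_fraction, "LAB",
                     ifelse(stats::runif(n) < 0.5, "HAB", "MAB"))

  rp <- spec$region_params
  tissue <- rp$region[rp$region != "blood_pool"]
  base_bp <- stats::setNames(rp$bp[match(tissue, rp$region)], tissue)
  true_bp <- matrix(rep(base_bp, each = n), n, length(tissue),
                    dimnames = list(id, tissue))
  true_bp <- true_bp + matrix(stats::rnorm(n * length(tissue), 0,
                                           effects$subject_sd),
                              n, length(tissue))
  true_bp[true_bp < 0] <- 0
  for (i in which(group == "anoxic")) {
    inc <- stats::runif(length(anoxic_regions()),
                        effects$anoxic_lo, effects$anoxic_hi)
    true_bp[i, anoxic_regions()] <- true_bp[i, anoxic_regions()] + inc
  }
  for (i in which(group == "traumatic")) {
    inc <- stats::runif(length(traumatic_regions()),
                        effects$traumatic_lo, effects$traumatic_hi)
    true_bp[i, traumatic_regions()] <- true_bp[i, traumatic_regions()] + inc
  }

  # CRS-R: decreasing logistic link on pallidal BP, noisy, clamped to 0-23
  crs_r <- rep(NA_integer_, n)
  state <- rep(NA_character_, n)
  patients <- which(group != "control")
  if (length(patients)) {
    lin <- 23 * stats::plogis(-(true_bp[patients, "globus_pallidum"] -
                                  effects$crsr_mid) / effects$crsr_scale)
    crs <- round(lin + stats::rnorm(length(patients), 0, effects$crsr_sd))
    crs <- pmin(pmax(crs, 0L), 23L)
    st <- ifelse(crs >= 18, "EMCS", ifelse(crs >= 8, "MCS", "VS_UWS"))
    dead <- crs < 8 & stats::runif(length(patients)) < 0.25
    st[dead] <- "deceased"
    crs[dead] <- 0L
    crs_r[patients] <- as.integer(crs)
    state[patients] <- st
  }
  outcome <- ifelse(is.na(state), NA_character_,
                    ifelse(state %in% c("MCS", "EMCS"),
                           "favourable", "unfavourable"))
  records <- data.frame(id = id, group = group, genotype = genotype,
                        crs_r = crs_r, state = state, outcome = outcome,
                        excluded_lab = genotype == "LAB",
                        stringsAsFactors = FALSE)
  measured_bp <- true_bp + matrix(stats::rnorm(n * length(tissue), 0,
                                               effects$measurement_sd),
                                  n, length(tissue), dimnames = dimnames(true_bp))

  out <- list(records = records, true_bp = true_bp,
              measured_bp = measured_bp, regions = tissue, spec = spec)

  if (images) {
    imgs <- vector("list", n)
    labels <- NULL; brain <- NULL
    for (i in seq_len(n)) {
      rpi <- rp
      tix <- match(tissue, rpi$region)
      rpi$bp[tix] <- true_bp[i, tissue]
      sp <- spec
      sp$region_params <- rpi
      sp$noise_scale <- effects$noise_scale
      sp$seed <- as.integer(seed) + i
      ph <- build_phantom(sp)
      imgs[[i]] <- ph$image
      if (is.null(labels)) { labels <- ph$labels; brain <- ph$brain_mask }
    }
    out$images <- stats::setNames(imgs, id)
    out$labels <- labels
    out$brain_mask <- brain
  }
  out
}

#' Per-subject 3D binding-potential maps from cohort ground truth
#'
#' Fast emulation of the end product of the kinetic pipeline: each subject's
#' BP map equals their regional ground truth plus i.i.d. voxel noise. Used
#' to exercise the voxel-wise statistics and the PLS outcome model at scale
#' without re-running the kinetic fits.
#'
#' @param cohort result of [simulate_cohort()]
#' @param voxel_sd SD of the additive voxel-level noise
#' @param seed integer seed
#' @return list with `maps` (named list of 3D arrays), `mask` (brain mask),
#'   `labels` ([label_map()])
#' @export
simulate_bp_maps <- function(cohort, voxel_sd = 0.3, seed = 1L) {
  spec <- cohort$spec
  rp <- spec$region_params
  masks <- region_boxes(rp$region, spec$dim3)
  labels <- array(0L, spec$dim3)
  nm <- character(0)
  for (i in seq_len(nrow(rp))) {
    labels[masks[[rp$region[i]]]] <- i
    nm[as.character(i)] <- rp$region[i]
  }
  tissue <- cohort$regions
  brain <- array(labels > 0L & nm[as.character(pmax(labels, 1L))] != "blood_pool",
                 spec$dim3)
  set.seed(as.integer(seed))
  n <- nrow(cohort$records)
  maps <- vector("list", n)
  for (s in seq_len(n)) {
    m <- array(NA_real_, spec$dim3)
    for (r in tissue) m[masks[[r]]] <- cohort$true_bp[s, r]
    m[brain] <- m[brain] + stats::rnorm(sum(brain), 0, voxel_sd)
    maps[[s]] <- m
  }
  list(maps = stats::setNames(maps, cohort$records$id), mask = brain,
       labels = label_map(labels, nm, spec$voxel_size))
}
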