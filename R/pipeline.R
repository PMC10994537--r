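#' Build an SVCA class set from control subjects
#'
#' Runs the class-creation step end to end for one binding-affinity group:
#' normalizes each control image, selects its blood voxels, extracts the
#' four per-subject class curves from the eroded anatomical masks, and
#' averages over retained (non-outlier) subjects.
#'
#' @param control_images list of raw [dynamic_image()]s, one per control
#' @param lmap a [label_map()] shared by the controls
#' @param brain_mask logical 3D mask
#' @param affinity_group `"HAB"` or `"MAB"`
#' @param erosion erosion iterations applied to the anatomical class masks
#' @param n_blood,window_s blood-class selection parameters
#'   (see [select_blood_voxels()])
#' @param outlier_mult outlier threshold (see [aggregate_classes()])
#' @return a [kinetic_class_set()]
#' @export
build_class_set <- function(control_images, lmap, brain_mask,
                            affinity_group, erosion = 1, n_blood = 40,
                            window_s = 180, outlier_mult = 3) {
  anat <- svca_masks(lmap, erosion)
  sets <- lapply(control_images, function(img) {
    nrm <- normalize_frames(img, brain_mask)
    masks <- c(list(blood = select_blood_voxels(nrm, brain_mask, n_blood,
                                                window_s)),
               anat)
    subject_class_curves(nrm, masks)
  })
  aggregate_classes(sets, affinity_group, outlier_mult)
}

#' Quantify one subject: unmixing, reference extraction, SRTM2 maps
#'
#' The per-subject half of the pipeline: normalizes the dynamic image,
#' decomposes it onto the SVCA classes by NNLS, thresholds the low-binding
#' weight ratio to find the pseudo-reference voxels, averages the raw
#' activity over them into the subject's reference curve, and fits SRTM2
#' voxel-wise.
#'
#' @param raw_image raw [dynamic_image()]
#' @param classes the subject's affinity group [kinetic_class_set()]
#' @param brain_mask logical 3D mask
#' @param ref_threshold weight-ratio threshold (see [reference_mask()])
#' @param ... further arguments passed to [parametric_map()]
#' @return list with `map` ([parametric_map()]), `ref` (the reference
#'   [tac()]), `ref_mask`, and `weights` ([nnls_unmix()] output)
#' @export
quantify_subject <- function(raw_image, classes, brain_mask,
                             ref_threshold = 0.9, ...) {
  nrm <- normalize_frames(raw_image, brain_mask)
  w <- nnls_unmix(nrm, classes, brain_mask)
  rmask <- reference_mask(w, ref_threshold)
  ref <- reference_tac(raw_image, rmask)
  map <- parametric_map(raw_image, ref, brain_mask, ...)
  list(map = map, ref = ref, ref_mask = rmask, weights = w)
}
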