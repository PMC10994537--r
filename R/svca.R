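#' SVCA kinetic class set
#'
#' The four supervised-cluster-analysis class curves for one binding-affinity
#' group: typical blood, specific-binding grey matter, non-specific-binding
#' grey matter and white matter, all built from frame-normalized control
#' images and sharing one schedule.
#'
#' @param blood,specific_gm,nonspecific_gm,white_matter [tac()] objects on a
#'   common schedule
#' @param affinity_group `"HAB"` or `"MAB"` (built independently per group)
#' @param n_controls_used number of control subjects retained in the average
#' @export
kinetic_class_set <- function(blood, specific_gm, nonspecific_gm,
                              white_matter, affinity_group,
                              n_controls_used) {
  curves <- list(blood = blood, specific_gm = specific_gm,
                 nonspecific_gm = nonspecific_gm, white_matter = white_matter)
  sched <- blood$schedule
  for (cl in curves)
    if (!schedules_equal(cl$schedule, sched))
      stop("all class curves must share one schedule")
  if (!affinity_group %in% c("HAB", "MAB"))
    stop("affinity_group must be 'HAB' or 'MAB'")
  structure(c(curves, list(schedule = sched, affinity_group = affinity_group,
                           n_controls_used = n_controls_used)),
            class = "kinetic_class_set")
}

#' @export
print.kinetic_class_set <- function(x, ...) {
  cat(sprintf("<kinetic_class_set> %s, %d frames, built from %d controls\n",
              x$affinity_group, n_frames(x$schedule), x$n_controls_used))
  invisible(x)
}

class_matrix <- function(classes) {
  cbind(blood = classes$blood$values,
        specific_gm = classes$specific_gm$values,
        nonspecific_gm = classes$nonspecific_gm$values,
        white_matter = classes$white_matter$values)
}

#' Select the early-hottest voxels as the blood class sample
#'
#' Picks the `n` in-mask voxels with the largest duration-weighted summed
#' activity over the frames that end within the first `window_s` seconds of
#' the acquisition (the bolus transit window, during which blood activity
#' dominates tissue). Ties are broken by lexicographic voxel index so the
#' selection is deterministic.
#'
#' @param norm_image frame-normalized [dynamic_image()] (see
#'   [normalize_frames()])
#' @param brain_mask logical 3D mask with at least `n` voxels
#' @param n number of voxels to select (default 40)
#' @param window_s early-activity window in seconds (default 180)
#' @return logical 3D mask with exactly `n` TRUE voxels
#' @export
select_blood_voxels <- function(norm_image, brain_mask, n = 40,
                                window_s = 180) {
  check_mask(norm_image, brain_mask)
  if (sum(brain_mask) < n)
    stop(sprintf("brain mask has %d voxels but %d are requested",
                 sum(brain_mask), n))
  sched <- norm_image$schedule
  early <- which(frame_end(sched) <= window_s + 1e-9)
  if (length(early) == 0) stop("no frame ends within the early window")
  Y <- image_matrix(norm_image)[early, , drop = FALSE]
  score <- as.vector(sched$durations[early] %*% Y)
  score[!as.vector(brain_mask)] <- -Inf
  ord <- order(score, seq_along(score), decreasing = c(TRUE, FALSE),
               method = "radix")
  sel <- ord[seq_len(n)]
  out <- array(FALSE, img_dim3(norm_image))
  out[sel] <- TRUE
  out
}

#' Per-subject SVCA class curves
#'
#' Mean normalized TAC per kinetic class for one subject, from the supplied
#' (already eroded) anatomical masks: `blood` (from
#' [select_blood_voxels()]), `thalamus` (specific-binding grey matter),
#' `cerebellum_gm` (non-specific-binding grey matter) and `wm` (white
#' matter).
#'
#' @param norm_image frame-normalized [dynamic_image()]
#' @param masks named list with logical masks `blood`, `thalamus`,
#'   `cerebellum_gm`, `wm`; extra entries are ignored
#' @return named list of four [tac()] objects (blood, specific_gm,
#'   nonspecific_gm, white_matter)
#' @export
subject_class_curves <- function(norm_image, masks) {
  need <- c(blood = "blood", specific_gm = "thalamus",
            nonspecific_gm = "cerebellum_gm", white_matter = "wm")
  out <- list()
  for (cl in names(need)) {
    m <- masks[[need[[cl]]]]
    if (is.null(m)) stop(sprintf("mask '%s' is missing", need[[cl]]))
    if (!any(m))
      stop(sprintf("mask for class '%s' is empty after erosion", cl))
    out[[cl]] <- extract_tac(norm_image, m)
  }
  out
}

#' Aggregate per-subject class curves into an SVCA class set
#'
#' Frame-wise average of the retained control subjects' curves, per affinity
#' group. A subject is excluded as an outlier when the root-mean-square
#' deviation of their non-specific-GM curve from the leave-one-out group
#' mean exceeds `outlier_mult` times the group median of those deviations
#' (a deterministic, scale-free stand-in for "significantly different
#' non-specific binding profile").
#'
#' @param per_subject_sets list of per-subject class-curve quadruples as
#'   returned by [subject_class_curves()]
#' @param affinity_group `"HAB"` or `"MAB"`
#' @param outlier_mult exclusion threshold multiplier (default 3)
#' @return a [kinetic_class_set()]; the integer indices of excluded subjects
#'   are attached as attribute `excluded`
#' @export
aggregate_classes <- function(per_subject_sets, affinity_group,
                              outlier_mult = 3) {
  ns <- length(per_subject_sets)
  if (ns < 2) stop("need at least 2 subjects to build a class set")
  sched <- per_subject_sets[[1]]$blood$schedule
  nsgm <- vapply(per_subject_sets, function(s) s$nonspecific_gm$values,
                 numeric(n_frames(sched)))
  rms <- vapply(seq_len(ns), function(i) {
    loo_mean <- rowMeans(nsgm[, -i, drop = FALSE])
    sqrt(mean((nsgm[, i] - loo_mean)^2))
  }, numeric(1))
  med <- stats::median(rms)
  excluded <- which(rms > outlier_mult * med)
  keep <- setdiff(seq_len(ns), excluded)
  if (length(keep) == 0) stop("all subjects excluded as outliers")
  avg <- function(cl) {
    v <- rowMeans(vapply(per_subject_sets[keep], function(s) s[[cl]]$values,
                         numeric(n_frames(sched))))
    tac(v, sched)
  }
  out <- kinetic_class_set(avg("blood"), avg("specific_gm"),
                           avg("nonspecific_gm"), avg("white_matter"),
                           affinity_group, n_controls_used = length(keep))
  attr(out, "excluded") <- excluded
  out
}

#' Build the eroded SVCA masks from a label map
#'
#' Convenience wrapper collecting the class masks the SVCA step needs from a
#' phantom (or segmentation-derived) label map and eroding each.
#'
#' @param lmap a [label_map()]
#' @param iterations erosion iterations (default 1)
#' @return named list of logical masks `thalamus`, `cerebellum_gm`, `wm`
#' @export
svca_masks <- function(lmap, iterations = 1) {
  list(thalamus = erode_mask(region_mask(lmap, "thalamus"), iterations),
       cerebellum_gm = erode_mask(region_mask(lmap, "cerebellum_gm"), iterations),
       wm = erode_mask(region_mask(lmap, "white_matter"), iterations))
}
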