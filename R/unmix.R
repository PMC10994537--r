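#' Voxel-wise non-negative least-squares unmixing onto the kinetic classes
#'
#' Decomposes each in-mask normalized voxel TAC as a non-negative weighted
#' combination of the four SVCA class curves, minimizing
#' `||TAC - sum_c w_c class_c||_2` subject to `w >= 0` (Lawson-Hanson NNLS).
#' Voxels outside the mask carry `NA` weights ("not computed"), not zeros.
#'
#' @param norm_image frame-normalized [dynamic_image()]
#' @param classes a [kinetic_class_set()] sharing the image's schedule
#' @param brain_mask logical 3D mask
#' @return object of class `weight_maps`: list of four 3D weight arrays
#'   (`blood`, `specific_gm`, `nonspecific_gm`, `white_matter`), a
#'   `residual` array (2-norm of the per-voxel residual) and the `mask`
#' @export
nnls_unmix <- function(norm_image, classes, brain_mask) {
  check_mask(norm_image, brain_mask)
  if (!schedules_equal(norm_image$schedule, classes$schedule))
    stop("image and class curves do not share a schedule")
  A <- class_matrix(classes)
  Y <- image_matrix(norm_image)
  vox <- which(as.vector(brain_mask))
  W <- matrix(NA_real_, length(vox), 4,
              dimnames = list(NULL, colnames(A)))
  res <- rep(NA_real_, length(vox))
  for (i in seq_along(vox)) {
    fit <- pracma::lsqnonneg(A, Y[, vox[i]])
    W[i, ] <- fit$x
    res[i] <- sqrt(fit$resid.norm)
  }
  d3 <- img_dim3(norm_image)
  as_map <- function(v) { m <- array(NA_real_, d3); m[vox] <- v; m }
  structure(list(blood = as_map(W[, 1]), specific_gm = as_map(W[, 2]),
                 nonspecific_gm = as_map(W[, 3]), white_matter = as_map(W[, 4]),
                 residual = as_map(res), mask = brain_mask),
            class = "weight_maps")
}

#' Pseudo-reference voxel mask from class weights
#'
#' The low-binding grey matter weight ratio is the non-specific-GM weight
#' over the sum of all four class weights; voxels where it exceeds the
#' threshold (default 0.9) form the subject's ad hoc reference region.
#' Voxels with zero total weight are excluded.
#'
#' @param weights a `weight_maps` object from [nnls_unmix()]
#' @param threshold ratio threshold (default 0.9)
#' @return logical 3D mask
#' @export
reference_mask <- function(weights, threshold = 0.9) {
  total <- weights$blood + weights$specific_gm + weights$nonspecific_gm +
    weights$white_matter
  ratio <- weights$nonspecific_gm / total
  out <- !is.na(ratio) & total > 0 & ratio > threshold
  if (!any(out))
    stop("reference mask is empty; consider relaxing the threshold")
  out
}

#' Subject-specific reference time-activity curve
#'
#' Mean raw (un-normalized) TAC over the pseudo-reference voxels. Kinetic
#' modelling needs activity units, so the reference curve is always taken
#' from the raw dynamic image, not from the z-scored image used for
#' unmixing.
#'
#' @param raw_image the un-normalized [dynamic_image()]
#' @param mask the reference voxel mask (see [reference_mask()])
#' @return a [tac()]
#' @export
reference_tac <- function(raw_image, mask) {
  extract_tac(raw_image, mask)
}
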