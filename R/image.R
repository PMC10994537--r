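#' Dynamic (4D) PET image
#'
#' Binds a 4D voxel activity array to its frame schedule and voxel geometry.
#' The affine maps 0-based voxel indices to world (scanner) millimetres, as
#' in the NIfTI convention.
#'
#' @param values 4D numeric array (x, y, z, frame), finite
#' @param schedule a [frame_schedule]; its length must equal the 4th dimension
#' @param voxel_size length-3 positive numeric, mm per axis
#' @param affine 4x4 voxel-to-world matrix; default diagonal from `voxel_size`
#' @return object of class `dynamic_image`
#' @export
dynamic_image <- function(values, schedule,
                          voxel_size = c(1, 1, 1),
                          affine = NULL) {
  if (length(dim(values)) != 4L) stop("values must be a 4D array")
  if (dim(values)[4] != n_frames(schedule))
    stop("number of frames does not match the schedule")
  if (!all(is.finite(values))) stop("values must be finite")
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  stopifnot(all(dim(affine) == c(4, 4)))
  structure(list(values = values, schedule = schedule,
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dynamic_image> %d x %d x %d voxels, %d frames, voxel %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

img_dim3 <- function(image) dim(image$values)[1:3]

#' Image geometry (grid dimensions, voxel size, affine)
#' @param image a `dynamic_image` or `label_map`
#' @export
img_geometry <- function(image) {
  if (inherits(image, "dynamic_image"))
    list(dim = img_dim3(image), voxel_size = image$voxel_size, affine = image$affine)
  else if (inherits(image, "label_map"))
    list(dim = dim(image$labels), voxel_size = image$voxel_size, affine = image$affine)
  else stop("no geometry for this object")
}

# frames x voxels matrix view of a dynamic image
image_matrix <- function(image) {
  d <- dim(image$values)
  t(matrix(image$values, prod(d[1:3]), d[4]))
}

#' Integer-labelled region map
#'
#' @param labels 3D integer array; 0 is background
#' @param names named character vector: names are region ids (as character),
#'   values are region names
#' @param voxel_size,affine geometry, as in [dynamic_image()]
#' @export
label_map <- function(labels, names, voxel_size = c(1, 1, 1), affine = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels < 0)) stop("labels must be non-negative (0 = background)")
  if (is.null(affine)) affine <- diag(c(voxel_size, 1))
  structure(list(labels = labels, names = names,
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "label_map")
}

#' Logical mask of one named region of a label map
#' @param lmap a [label_map()]
#' @param region region name (must appear in `lmap$names`)
#' @export
region_mask <- function(lmap, region) {
  id <- names(lmap$names)[match(region, lmap$names)]
  if (is.na(id)) stop(sprintf("region '%s' not present in label map", region))
  lmap$labels == as.integer(id)
}

#' Time-activity curve
#' @param values per-frame activity
#' @param schedule a [frame_schedule]
#' @export
tac <- function(values, schedule) {
  if (length(values) != n_frames(schedule))
    stop("TAC length does not match the schedule")
  if (!all(is.finite(values))) stop("TAC values must be finite")
  structure(list(values = as.numeric(values), schedule = schedule), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %d frames, range [%.3g, %.3g]\n",
              n_frames(x$schedule), min(x$values), max(x$values)))
  invisible(x)
}

#' Mean regional time-activity curve
#'
#' @param image a [dynamic_image()]
#' @param mask logical 3D array on the same grid; must select at least one voxel
#' @return a [tac()] of per-frame means over the mask
#' @export
extract_tac <- function(image, mask) {
  check_mask(image, mask)
  if (!any(mask)) stop("mask is empty")
  Y <- image_matrix(image)  # frames x voxels
  tac(rowMeans(Y[, as.vector(mask), drop = FALSE]), image$schedule)
}

check_mask <- function(image, mask) {
  if (!is.logical(mask)) stop("mask must be logical")
  if (!all(dim(mask) == img_dim3(image)))
    stop("mask grid does not match the image")
}

#' Per-frame z-score normalization within a brain mask
#'
#' Each frame is centred and scaled by the mean and population standard
#' deviation of the in-mask voxels of that frame, so that within the brain
#' every frame has mean 0 and SD 1. Voxels outside the mask are set to 0 and
#' flagged invalid via the `valid` element; they are bookkeeping, not data.
#'
#' @param image a [dynamic_image()]
#' @param brain_mask logical 3D array with at least 2 voxels
#' @return a `dynamic_image` with an extra element `valid` (the brain mask)
#' @export
normalize_frames <- function(image, brain_mask) {
  check_mask(image, brain_mask)
  if (sum(brain_mask) < 2) stop("brain mask must contain at least 2 voxels")
  d <- dim(image$values)
  out <- array(0, d)
  sel <- as.vector(brain_mask)
  for (f in seq_len(d[4])) {
    v <- image$values[, , , f][sel]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population SD
    if (s == 0)
      stop(sprintf("frame %d has zero standard deviation within the brain mask", f))
    fr <- array(0, d[1:3])
    fr[sel] <- (v - m) / s
    out[, , , f] <- fr
  }
  res <- dynamic_image(out, image$schedule, image$voxel_size, image$affine)
  res$valid <- brain_mask
  res
}

#' Morphological erosion of a voxel mask
#'
#' Face-connected (6-neighbourhood) erosion: a voxel survives one iteration
#' if all six face neighbours (and itself) are inside the mask; grid borders
#' count as background. Used to shrink anatomical regions before class-curve
#' extraction to limit partial-volume contamination.
#'
#' @param mask logical 3D array
#' @param iterations non-negative integer; 0 is the identity
#' @return logical 3D array, a subset of `mask` (possibly empty)
#' @export
erode_mask <- function(mask, iterations = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (iterations < 0 || iterations != round(iterations))
    stop("iterations must be a non-negative integer")
  m <- mask
  d <- dim(m)
  for (it in seq_len(iterations)) {
    shifted <- function(dx, dy, dz) {
      out <- array(FALSE, d)
      xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
      xi <- xs + dx; yi <- ys + dy; zi <- zs + dz
      okx <- xi >= 1 & xi <= d[1]; oky <- yi >= 1 & yi <= d[2]; okz <- zi >= 1 & zi <= d[3]
      out[xs[okx], ys[oky], zs[okz]] <- m[xi[okx], yi[oky], zi[okz], drop = FALSE]
      out
    }
    m <- m &
      shifted(1, 0, 0) & shifted(-1, 0, 0) &
      shifted(0, 1, 0) & shifted(0, -1, 0) &
      shifted(0, 0, 1) & shifted(0, 0, -1)
  }
  m
}

# world-mm coordinates of all voxel centres; rows = voxels in array order
voxel_world_coords <- function(geometry) {
  d <- geometry$dim
  idx <- as.matrix(expand.grid(x = seq_len(d[1]) - 1,
                               y = seq_len(d[2]) - 1,
                               z = seq_len(d[3]) - 1))
  t(geometry$affine %*% t(cbind(idx, 1)))[, 1:3, drop = FALSE]
}

#' Spherical volume of interest
#'
#' Selects the voxels whose centre lies within `radius` mm of a world-space
#' point; used to place spherical sample VOIs in and around focal lesions.
#'
#' @param centre length-3 world coordinates, mm
#' @param radius sphere radius, mm (> 0)
#' @param geometry list with `dim`, `voxel_size`, `affine` (see [img_geometry()])
#' @return logical 3D mask
#' @export
sphere_voi <- function(centre, radius, geometry) {
  if (radius <= 0) stop("radius must be positive")
  xyz <- voxel_world_coords(geometry)
  d2 <- (xyz[, 1] - centre[1])^2 + (xyz[, 2] - centre[2])^2 + (xyz[, 3] - centre[3])^2
  inside <- d2 <= radius^2
  if (!any(inside))
    stop("sphere does not contain any voxel centre (entirely outside the grid?)")
  array(inside, geometry$dim)
}
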