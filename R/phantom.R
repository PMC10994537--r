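#' Default regional kinetic parameters for the digital phantom
#'
#' One row per named VOI of the analysis. `R1` and baseline `bp` are chosen
#' as plausible grey/white-matter values (they are synthetic defaults, not
#' estimates from any dataset): delivery near unity for grey matter, lower
#' for white matter; baseline binding 0.2-1.0 with the thalamus (the
#' specific-binding class region) highest; the cerebellar grey matter - the
#' pseudo-reference region the SVCA pipeline is designed to find - has
#' bp = 0 so that reference-tissue quantification of the phantom is exactly
#' identifiable. The blood pool carries a scaled input-function curve rather
#' than tissue kinetics.
#'
#' @param k2p reference efflux rate shared by all regions, 1/min
#' @return data.frame with columns region, R1, bp, k2p
#' @export
default_region_params <- function(k2p = 0.05) {
  regions <- c("brainstem", "thalamus", "caudate", "globus_pallidum",
               "putamen", "corpus_callosum", "ACC", "PCC", "mPFC",
               "precuneus", "superior_parietal", "cuneus", "hippocampus",
               "precentral", "cerebellum_gm", "blood_pool", "white_matter")
  R1 <- c(0.95, 1.05, 1.10, 1.00, 1.05, 0.85, 1.10, 1.05, 1.00,
          1.05, 1.00, 0.95, 0.90, 1.00, 1.00, NA, 0.80)
  bp <- c(0.45, 1.00, 0.50, 0.50, 0.55, 0.30, 0.40, 0.45, 0.40,
          0.40, 0.35, 0.35, 0.50, 0.25, 0.00, NA, 0.30)
  data.frame(region = regions, R1 = R1, bp = bp, k2p = k2p,
             stringsAsFactors = FALSE)
}

# Disjoint cuboid region boxes laid out on a 4 x 5 cell raster in x-y.
# Returns a list of logical masks, one per region name, plus validates
# that the grid can hold them.
region_boxes <- function(regions, dim3) {
  nx <- 4; ny <- 5
  if (length(regions) > nx * ny) stop("too many regions for the box raster")
  cw <- floor(dim3[1] / nx); ch <- floor(dim3[2] / ny)
  bx <- cw - 2; by <- ch - 2           # leave a 1-voxel gap between boxes
  z0 <- max(1, floor(dim3[3] / 4)); z1 <- min(dim3[3], z0 + max(4, floor(dim3[3] / 2)))
  if (bx < 1 || by < 1 || z1 - z0 < 1) stop("grid too small for the phantom layout")
  out <- list()
  for (i in seq_along(regions)) {
    cx <- (i - 1) %% nx
    cy <- (i - 1) %/% nx
    m <- array(FALSE, dim3)
    m[(cx * cw + 2):(cx * cw + 1 + bx),
      (cy * ch + 2):(cy * ch + 1 + by),
      z0:z1] <- TRUE
    out[[regions[i]]] <- m
  }
  out
}

#' Specification of a synthetic dynamic-PET phantom
#'
#' @param dim3 grid size (3 integers)
#' @param voxel_size mm, isotropic scalar or length-3
#' @param schedule a [frame_schedule()]
#' @param region_params data.frame as [default_region_params()]
#' @param K1_ref absolute influx of the reference tissue, 1/min
#' @param blood_scale scale applied to the input function for the blood pool
#' @param noise_scale multiplier of the frame-variance noise model
#'   (see [add_noise()]); 0 = noiseless
#' @param dt_s fine simulation grid step, seconds
#' @param seed RNG seed used when noise is added
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(dim3 = c(32, 32, 16), voxel_size = 4,
                         schedule = dpa_frame_schedule(),
                         region_params = default_region_params(),
                         K1_ref = 0.1, blood_scale = 1.0,
                         noise_scale = 0, dt_s = 1, seed = 1L) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  structure(list(dim3 = dim3, voxel_size = voxel_size, schedule = schedule,
                 region_params = region_params, K1_ref = K1_ref,
                 blood_scale = blood_scale, noise_scale = noise_scale,
                 dt_s = dt_s, seed = seed),
            class = "phantom_spec")
}

#' Build a dynamic-PET phantom with known regional kinetics
#'
#' Every tissue region's noiseless voxel TAC is the SRTM forward curve of its
#' parameters driven by the (noiseless) reference fine curve; the blood-pool
#' region carries the scaled input function. Optionally adds frame-variance
#' scaled Gaussian noise (seeded, reproducible).
#'
#' @param spec a [phantom_spec()]
#' @param masks optional named list of region masks (defaults to the built-in
#'   cuboid layout); must be pairwise disjoint
#' @return list with elements `image` ([dynamic_image()]), `labels`
#'   ([label_map()]), `truth` (data.frame region, R1, k2, k2a, k2p, bp,
#'   n_voxels), `brain_mask`, and `ref_fine` (the noiseless fine-grid
#'   reference curve)
#' @export
build_phantom <- function(spec, masks = NULL) {
  rp <- spec$region_params
  if (is.null(masks)) masks <- region_boxes(rp$region, spec$dim3)
  if (!setequal(names(masks), rp$region))
    stop("masks must cover exactly the regions of region_params")
  occ <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(occ > 1L)) stop("region masks overlap")

  t_s <- fine_times(spec$schedule, spec$dt_s)
  ref_fine <- reference_fine(spec$schedule, spec$K1_ref, rp$k2p[1], spec$dt_s)
  nf <- n_frames(spec$schedule)
  vals <- array(0, c(spec$dim3, nf))
  labels <- array(0L, spec$dim3)
  nm <- character(0)
  truth <- list()
  for (i in seq_len(nrow(rp))) {
    region <- rp$region[i]
    m <- masks[[region]]
    labels[m] <- i
    nm[as.character(i)] <- region
    if (region == "blood_pool") {
      curve <- frame_average(spec$blood_scale * feng_input(t_s / 60),
                             spec$schedule, t_s)
      truth[[i]] <- data.frame(region = region, R1 = NA, k2 = NA, k2a = NA,
                               k2p = NA, bp = NA, n_voxels = sum(m))
    } else {
      pars <- kinetic_params(rp$R1[i], rp$bp[i], rp$k2p[i])
      curve <- srtm_forward(ref_fine, pars, spec$schedule, spec$dt_s)$values
      truth[[i]] <- data.frame(region = region, R1 = pars$R1, k2 = pars$k2,
                               k2a = pars$k2a, k2p = pars$k2p, bp = pars$bp,
                               n_voxels = sum(m))
    }
    sel <- as.vector(m)
    for (f in seq_len(nf)) {
      fr <- vals[, , , f]
      fr[sel] <- curve[f]
      vals[, , , f] <- fr
    }
  }
  img <- dynamic_image(vals, spec$schedule, spec$voxel_size)
  brain <- labels > 0L
  if (spec$noise_scale > 0)
    img <- add_noise(img, spec$noise_scale, seed = spec$seed, brain_mask = brain)
  list(image = img,
       labels = label_map(labels, nm, spec$voxel_size),
       truth = do.call(rbind, truth),
       brain_mask = brain,
       ref_fine = ref_fine)
}

#' Add frame-variance scaled Gaussian noise to a dynamic image
#'
#' The per-frame noise SD follows the standard PET frame-variance proxy
#' `sd_f = scale * sqrt(mean brain activity in frame f / frame duration)`
#' (duration in minutes): short early frames and low-count late frames are
#' noisier. Seeded and reproducible.
#'
#' @param image a [dynamic_image()]
#' @param scale noise multiplier (0 = identity)
#' @param seed RNG seed
#' @param brain_mask mask over which the per-frame mean activity is taken
#'   (default: whole grid)
#' @return a `dynamic_image` of the same geometry
#' @export
add_noise <- function(image, scale, seed = 1L, brain_mask = NULL) {
  if (scale < 0) stop("noise scale must be non-negative")
  if (scale == 0) return(image)
  d <- dim(image$values)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, d[1:3])
  check_mask(image, brain_mask)
  out <- image$values
  dur_min <- image$schedule$durations / 60
  set.seed(as.integer(seed))
  for (f in seq_len(d[4])) {
    mu <- mean(image$values[, , , f][brain_mask])
    sdf <- scale * sqrt(max(mu, 0) / dur_min[f])
    out[, , , f] <- out[, , , f] + array(stats::rnorm(prod(d[1:3]), 0, sdf), d[1:3])
  }
  dynamic_image(out, image$schedule, image$voxel_size, image$affine)
}

#' Per-frame nominal noise SD of the [add_noise()] model
#' @keywords internal
noise_frame_sd <- function(image, scale, brain_mask = NULL) {
  d <- dim(image$values)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, d[1:3])
  vapply(seq_len(d[4]), function(f) {
    mu <- mean(image$values[, , , f][brain_mask])
    scale * sqrt(max(mu, 0) / (image$schedule$durations[f] / 60))
  }, numeric(1))
}
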