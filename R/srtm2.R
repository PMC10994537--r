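#' Default basis grid of apparent efflux rates
#'
#' 256 log-spaced `k2a` values on [0.006, 0.6] 1/min, bracketing plausible
#' human TSPO tracer kinetics.
#' @param n number of grid points
#' @param lo,hi grid range, 1/min
#' @export
default_k2a_grid <- function(n = 256, lo = 0.006, hi = 0.6) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# Reconstruct a fine-grid reference curve from a frame-level TAC.
# Starts from piecewise-linear interpolation through (0, 0) and the frame
# mid-times, then iteratively adjusts the knot values until the
# frame-averages of the interpolant reproduce the measured frame values
# (frames record averages, not instantaneous samples; without the
# correction the bolus frames are systematically distorted).
interp_ref_fine <- function(ref, dt_s = 1, iterations = 20) {
  sched <- ref$schedule
  t_fine <- fine_times(sched, dt_s)
  W <- frame_weights(sched, t_fine)
  knots <- c(0, frame_mid(sched))
  v <- ref$values
  for (it in seq_len(iterations)) {
    fine <- stats::approx(x = knots, y = c(0, v), xout = t_fine, rule = 2)$y
    favg <- as.vector(W %*% fine)
    v <- v + (ref$values - favg)
  }
  stats::approx(x = knots, y = c(0, v), xout = t_fine, rule = 2)$y
}

# Precompute the frame-averaged basis: x1 = frame-averaged reference,
# B[, j] = frame-averaged conv(ref_fine, exp(-k2a_j t)).
srtm_basis <- function(ref_fine, schedule, k2a_grid, dt_s = 1) {
  t_fine <- fine_times(schedule, dt_s)
  if (length(ref_fine) != length(t_fine))
    stop("ref_fine length does not match the schedule's fine grid")
  if (max(abs(ref_fine)) == 0) stop("reference curve is identically zero")
  W <- frame_weights(schedule, t_fine)
  x1 <- as.vector(W %*% ref_fine)
  B <- vapply(k2a_grid,
              function(k) as.vector(W %*% conv_exp(ref_fine, dt_s / 60, k)),
              numeric(n_frames(schedule)))
  list(x1 = x1, B = B, k2a_grid = k2a_grid,
       ref_fine = ref_fine, W = W, dt_s = dt_s)
}

# First-pass SRTM (three-parameter) basis fit on a frames x voxels matrix.
# For each k2a the model is y = R1 * x1 + theta2 * b_j; the best grid point
# per voxel minimizes the residual sum of squares.
srtm_fit_mat <- function(Y, basis) {
  x1 <- basis$x1; B <- basis$B; grid <- basis$k2a_grid
  nv <- ncol(Y)
  yy <- colSums(Y^2)
  r1y <- as.vector(crossprod(x1, Y))          # x1'y per voxel
  x11 <- sum(x1^2)
  best_rss <- rep(Inf, nv); best_j <- rep(1L, nv)
  best_r1 <- rep(NA_real_, nv); best_th <- rep(NA_real_, nv)
  for (j in seq_along(grid)) {
    bj <- B[, j]
    b2y <- as.vector(crossprod(bj, Y))
    g12 <- sum(x1 * bj); g22 <- sum(bj^2)
    det <- x11 * g22 - g12^2
    if (det <= .Machine$double.eps * x11 * g22) next
    r1 <- (g22 * r1y - g12 * b2y) / det
    th <- (x11 * b2y - g12 * r1y) / det
    rss <- yy - r1 * r1y - th * b2y
    upd <- rss < best_rss
    best_rss[upd] <- rss[upd]; best_j[upd] <- j
    best_r1[upd] <- r1[upd]; best_th[upd] <- th[upd]
  }
  k2a <- grid[best_j]
  k2 <- best_th + best_r1 * k2a
  list(R1 = best_r1, k2 = k2, k2a = k2a, bp = k2 / k2a - 1,
       k2p = k2 / best_r1, rss = pmax(best_rss, 0))
}

# SRTM2 (one-parameter) basis fit with fixed reference efflux k2p:
# y = R1 * (x1 + (k2p - k2a_j) * b_j). After the grid search, k2a is
# refined per voxel by parabolic interpolation of the residual profile in
# log(k2a) between the two neighbouring grid points, with the exact
# regressor rebuilt at the refined value; the refinement is kept only when
# it lowers the residual, so the grid solution is a guaranteed upper bound.
srtm2_fit_mat <- function(Y, basis, k2p_fixed, refine = TRUE) {
  if (k2p_fixed <= 0) stop("k2p_fixed must be positive")
  x1 <- basis$x1; B <- basis$B; grid <- basis$k2a_grid
  nv <- ncol(Y)
  yy <- colSums(Y^2)
  ng <- length(grid)
  rss_all <- matrix(Inf, ng, nv)
  w_all <- matrix(NA_real_, ng, nv)
  for (j in seq_len(ng)) {
    z <- x1 + (k2p_fixed - grid[j]) * B[, j]
    zz <- sum(z^2)
    if (zz <= 0) next
    zy <- as.vector(crossprod(z, Y))
    w_all[j, ] <- zy / zz
    rss_all[j, ] <- yy - zy^2 / zz
  }
  best_j <- apply(rss_all, 2, which.min)
  best_rss <- rss_all[cbind(best_j, seq_len(nv))]
  best_r1 <- w_all[cbind(best_j, seq_len(nv))]
  k2a <- grid[best_j]

  if (refine && !is.null(basis$ref_fine)) {
    interior <- which(best_j > 1L & best_j < ng)
    if (length(interior)) {
      lx <- log(grid)
      j0 <- best_j[interior]
      y0 <- rss_all[cbind(j0 - 1L, interior)]
      y1 <- rss_all[cbind(j0, interior)]
      y2 <- rss_all[cbind(j0 + 1L, interior)]
      x0 <- lx[j0 - 1L]; x1g <- lx[j0]; x2 <- lx[j0 + 1L]
      denom <- (y0 - y1) * (x1g - x2) - (y1 - y2) * (x0 - x1g)
      xv <- ifelse(abs(denom) > 0,
                   ((y0 - y1) * (x1g^2 - x2^2) - (y1 - y2) * (x0^2 - x1g^2)) /
                     (2 * denom),
                   x1g)
      xv <- pmin(pmax(xv, x0), x2)
      k2a_new <- exp(xv)
      W <- basis$W
      dtm <- basis$dt_s / 60
      for (ii in seq_along(interior)) {
        v <- interior[ii]
        bz <- as.vector(W %*% conv_exp(basis$ref_fine, dtm, k2a_new[ii]))
        z <- x1 + (k2p_fixed - k2a_new[ii]) * bz
        zz <- sum(z^2)
        if (zz <= 0) next
        zy <- sum(z * Y[, v])
        rss <- yy[v] - zy^2 / zz
        if (rss < best_rss[v]) {
          best_rss[v] <- rss
          best_r1[v] <- zy / zz
          k2a[v] <- k2a_new[ii]
        }
      }
    }
  }
  list(R1 = best_r1, k2 = best_r1 * k2p_fixed, k2a = k2a,
       bp = best_r1 * k2p_fixed / k2a - 1, k2p = rep(k2p_fixed, nv),
       rss = pmax(best_rss, 0))
}

#' First-pass SRTM fit of a single time-activity curve
#'
#' Basis-function fit of the three-parameter simplified reference tissue
#' model: for each candidate apparent efflux `k2a` on the grid, a linear
#' least-squares fit of the TAC on the reference curve and its exponential
#' convolution; the grid point with minimal residual wins. Returns R1, k2,
#' k2a, the binding potential `bp = k2/k2a - 1` and the per-fit reference
#' efflux `k2p = k2/R1`.
#'
#' @param tac_obj target [tac()]
#' @param ref reference [tac()] on the same schedule
#' @param k2a_grid candidate apparent efflux rates, 1/min
#' @param ref_fine optional fine-grid reference curve (1-s step); when
#'   absent, the reference TAC is linearly interpolated to the fine grid
#' @param dt_s fine grid step, seconds
#' @return a list with R1, k2, k2a, k2p, bp, rss
#' @export
srtm_fit <- function(tac_obj, ref, k2a_grid = default_k2a_grid(),
                     ref_fine = NULL, dt_s = 1) {
  if (!schedules_equal(tac_obj$schedule, ref$schedule))
    stop("target and reference TACs do not share a schedule")
  if (is.null(ref_fine)) ref_fine <- interp_ref_fine(ref, dt_s)
  basis <- srtm_basis(ref_fine, ref$schedule, k2a_grid, dt_s)
  fit <- srtm_fit_mat(matrix(tac_obj$values, ncol = 1), basis)
  lapply(fit, `[`, 1)
}

#' SRTM2 fit of a single time-activity curve with fixed reference efflux
#'
#' One-parameter basis fit: with `k2p` fixed globally, each candidate `k2a`
#' yields the regressor `ref + (k2p - k2a) * conv(ref, exp(-k2a t))` whose
#' single coefficient is R1; `bp = R1*k2p/k2a - 1`.
#'
#' @inheritParams srtm_fit
#' @param k2p_fixed globally fixed reference efflux rate, 1/min
#' @export
srtm2_fit <- function(tac_obj, ref, k2p_fixed,
                      k2a_grid = default_k2a_grid(), ref_fine = NULL,
                      dt_s = 1) {
  if (!schedules_equal(tac_obj$schedule, ref$schedule))
    stop("target and reference TACs do not share a schedule")
  if (is.null(ref_fine)) ref_fine <- interp_ref_fine(ref, dt_s)
  basis <- srtm_basis(ref_fine, ref$schedule, k2a_grid, dt_s)
  fit <- srtm2_fit_mat(matrix(tac_obj$values, ncol = 1), basis, k2p_fixed)
  lapply(fit, `[`, 1)
}

#' Estimate the global reference efflux rate
#'
#' First-pass SRTM over all in-mask voxels, then the median of the
#' per-voxel `k2p = k2/R1` over voxels whose fitted binding potential
#' exceeds `bp_floor` (near-zero-binding voxels carry almost no information
#' about `k2p` and are excluded).
#'
#' @param image raw [dynamic_image()]
#' @param ref reference [tac()]
#' @param mask logical 3D mask of voxels to fit
#' @param bp_floor minimum first-pass bp for a voxel to enter the median
#' @param k2a_grid candidate apparent efflux rates
#' @param ref_fine,dt_s as in [srtm_fit()]
#' @return scalar k2p, 1/min
#' @export
estimate_global_k2p <- function(image, ref, mask, bp_floor = 0.1,
                                k2a_grid = default_k2a_grid(),
                                ref_fine = NULL, dt_s = 1) {
  check_mask(image, mask)
  if (!any(mask)) stop("mask is empty")
  if (is.null(ref_fine)) ref_fine <- interp_ref_fine(ref, dt_s)
  basis <- srtm_basis(ref_fine, image$schedule, k2a_grid, dt_s)
  Y <- image_matrix(image)[, as.vector(mask), drop = FALSE]
  fit <- srtm_fit_mat(Y, basis)
  sel <- is.finite(fit$k2p) & fit$bp > bp_floor & fit$R1 > 0
  if (!any(sel))
    stop("no voxels above the bp floor; cannot estimate global k2p")
  stats::median(fit$k2p[sel])
}

#' Voxel-wise SRTM2 parametric maps
#'
#' The full quantification step: estimates the global reference efflux rate
#' with a first-pass SRTM, fixes it, and refits every in-mask voxel with the
#' one-parameter SRTM2 basis, producing binding-potential (`bp`), delivery
#' (`r1`) and apparent-efflux (`k2a`) maps. Negative bp values are retained
#' by default so that downstream group statistics stay unbiased; set
#' `clip_negative = TRUE` to floor them at 0.
#'
#' @param image raw [dynamic_image()]
#' @param ref reference [tac()] (from [reference_tac()])
#' @param brain_mask logical 3D mask
#' @param k2a_grid candidate apparent efflux rates
#' @param bp_floor floor used by [estimate_global_k2p()]
#' @param k2p_fixed optional: skip the first pass and use this value
#' @param clip_negative if TRUE, negative bp values are set to 0
#' @param ref_fine,dt_s as in [srtm_fit()]
#' @return object of class `parametric_map` with 3D arrays `bp`, `r1`,
#'   `k2a`, `fit_residual`, scalar `k2p_global`, and the `mask`
#' @export
parametric_map <- function(image, ref, brain_mask,
                           k2a_grid = default_k2a_grid(), bp_floor = 0.1,
                           k2p_fixed = NULL, clip_negative = FALSE,
                           ref_fine = NULL, dt_s = 1) {
  check_mask(image, brain_mask)
  if (is.null(ref_fine)) ref_fine <- interp_ref_fine(ref, dt_s)
  basis <- srtm_basis(ref_fine, image$schedule, k2a_grid, dt_s)
  vox <- which(as.vector(brain_mask))
  Y <- image_matrix(image)[, vox, drop = FALSE]
  if (is.null(k2p_fixed)) {
    first <- srtm_fit_mat(Y, basis)
    sel <- is.finite(first$k2p) & first$bp > bp_floor & first$R1 > 0
    if (!any(sel))
      stop("no voxels above the bp floor; cannot estimate global k2p")
    k2p_fixed <- stats::median(first$k2p[sel])
  }
  fit <- srtm2_fit_mat(Y, basis, k2p_fixed)
  if (clip_negative) fit$bp <- pmax(fit$bp, 0)
  d3 <- img_dim3(image)
  as_map <- function(v) { m <- array(NA_real_, d3); m[vox] <- v; m }
  structure(list(bp = as_map(fit$bp), r1 = as_map(fit$R1),
                 k2a = as_map(fit$k2a), fit_residual = as_map(fit$rss),
                 k2p_global = k2p_fixed, mask = brain_mask),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %d fitted voxels, k2p_global = %.4f /min, bp range [%.2f, %.2f]\n",
              sum(x$mask), x$k2p_global,
              min(x$bp, na.rm = TRUE), max(x$bp, na.rm = TRUE)))
  invisible(x)
}
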