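# Independent oracles and shared fixtures for the test suite.
# Oracles are deliberately written with different algorithms from the
# package implementation they check.

# Exhaustive-support NNLS oracle: for every subset S of columns solve the
# unconstrained least squares restricted to S, keep solutions that are
# non-negative, return the feasible solution with minimal residual.
# Exact for small column counts; independent of Lawson-Hanson.
nnls_oracle <- function(A, y) {
  p <- ncol(A)
  best <- list(x = rep(0, p), rss = sum(y^2))
  for (k in seq_len(2^p - 1)) {
    S <- which(bitwAnd(k, 2^(seq_len(p) - 1)) > 0)
    As <- A[, S, drop = FALSE]
    coef <- tryCatch(qr.solve(As, y), error = function(e) NULL)
    if (is.null(coef) || any(coef < -1e-12)) next
    rss <- sum((y - As %*% coef)^2)
    if (rss < best$rss - 1e-14) {
      x <- rep(0, p); x[S] <- pmax(coef, 0)
      best <- list(x = x, rss = rss)
    }
  }
  best
}

# Brute-force lattice count of voxel centres inside a sphere
sphere_count_oracle <- function(radius, voxel = 1) {
  r <- ceiling(radius / voxel)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r) * voxel
  sum(g$x^2 + g$y^2 + g$z^2 <= radius^2)
}

# Short acquisition used where full 60-min schedules are unnecessary
short_schedule <- function() {
  frame_schedule(list(c(4, 10), c(4, 30), c(4, 110)))  # 12 frames, 600 s
}

# Default noiseless phantom, built once per test run
cached <- local({
  env <- new.env()
  function(key, make) {
    if (is.null(env[[key]])) env[[key]] <- make()
    env[[key]]
  }
})

noiseless_phantom <- function() {
  cached("phantom", function() build_phantom(phantom_spec()))
}

# Full noiseless pipeline products shared across test files
noiseless_pipeline <- function() {
  cached("pipeline", function() {
    ph <- noiseless_phantom()
    ctrl <- lapply(1:3, function(i) ph$image)
    cls <- build_class_set(ctrl, ph$labels, ph$brain_mask, "HAB")
    q <- quantify_subject(ph$image, cls, ph$brain_mask)
    list(phantom = ph, classes = cls, quant = q)
  })
}

# Synthetic four-class curve set on the short schedule (linearly
# independent by construction)
toy_classes <- function() {
  sched <- short_schedule()
  tmid <- frame_mid(sched, "min")
  kinetic_class_set(
    blood = tac(10 * exp(-1.5 * tmid), sched),
    specific_gm = tac(3 * (1 - exp(-0.8 * tmid)), sched),
    nonspecific_gm = tac(2 * (1 - exp(-2 * tmid)) * exp(-0.05 * tmid), sched),
    white_matter = tac(1.2 * (1 - exp(-0.4 * tmid)), sched),
    affinity_group = "HAB", n_controls_used = 1)
}

# dynamic_image whose voxel TACs are the columns of `curves` (frames x n)
image_from_curves <- function(curves, sched) {
  n <- ncol(curves)
  d <- c(n, 1, 1)
  vals <- array(0, c(d, n_frames(sched)))
  for (f in seq_len(n_frames(sched))) vals[, 1, 1, f] <- curves[f, ]
  dynamic_image(vals, sched)
}
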