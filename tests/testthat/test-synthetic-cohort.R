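test_that("the input function is a causal single-peak bolus curve", {
  expect_equal(feng_input(0), 0)
  expect_error(feng_input(-1), "non-negative")

  t <- seq(0, 60, by = 1 / 60)
  cp <- feng_input(t)
  expect_true(all(is.finite(cp)))
  expect_gt(sum(cp) * 1 / 60, 0)

  # single peak: rises then decays monotonically after the maximum
  pk <- which.max(cp)
  expect_true(all(diff(cp[1:pk]) > 0))
  expect_true(all(diff(cp[pk:length(cp)]) < 0))

  # peak location matches an independent analytic maximization
  f <- function(tt) -feng_input(tt)
  opt <- optimize(f, c(0, 5))
  expect_equal(t[pk], opt$minimum, tolerance = 2 / 60)
})

test_that("the simulated reference TAC solves the one-tissue compartment model", {
  sched <- short_schedule()
  z <- simulate_reference_tac(sched, K1 = 0, k2p = 0.05)
  expect_equal(z$values, rep(0, n_frames(sched)))

  one <- simulate_reference_tac(sched, K1 = 0.1, k2p = 0.05)
  two <- simulate_reference_tac(sched, K1 = 0.2, k2p = 0.05)
  expect_equal(two$values, 2 * one$values, tolerance = 1e-12)

  # independent ODE oracle (adaptive LSODA at 0.1-s output step)
  k2p <- 0.05; K1 <- 0.1
  t_out <- seq(0, total_duration(sched), by = 0.1)
  sol <- deSolve::ode(
    y = c(C = 0), times = t_out,
    func = function(t, y, parms) {
      list(K1 * feng_input(t / 60) / 60 - k2p / 60 * y)
    }, parms = NULL, rtol = 1e-10, atol = 1e-12)
  oracle <- frame_average(sol[, "C"], sched, t_out)
  rel <- abs(one$values - oracle) / max(oracle)
  expect_lt(max(rel), 1e-3)
})

test_that("the SRTM forward model collapses to the reference when binding vanishes", {
  sched <- short_schedule()
  ref <- simulate_reference_tac(sched, 0.1, 0.05)
  rf <- attr(ref, "fine")

  ident <- srtm_forward(rf, kinetic_params(1, 0, 0.05), sched)
  expect_equal(ident$values, ref$values, tolerance = 1e-12)

  # linear scaling in R1 at fixed k2a (bp adjusts so k2a stays at 0.03)
  p1 <- kinetic_params(0.6, 0.6 * 0.05 / 0.03 - 1, 0.05)
  p2 <- kinetic_params(1.2, 1.2 * 0.05 / 0.03 - 1, 0.05)
  stopifnot(abs(p1$k2a - 0.03) < 1e-12, abs(p2$k2a - 0.03) < 1e-12)
  a <- srtm_forward(rf, p1, sched)
  b <- srtm_forward(rf, p2, sched)
  expect_equal(b$values, 2 * a$values, tolerance = 1e-10)

  # independent direct-summation trapezoidal convolution oracle at 0.1 s:
  # conv(t) = int_0^t ref(s) exp(-k2a (t - s)) ds with time in minutes
  pars <- kinetic_params(1, 1.5, 0.05)
  dt <- 0.1
  tt <- seq(0, total_duration(sched), by = dt)
  rf01 <- approx(fine_times(sched, 1), rf, tt)$y
  n <- length(tt)
  conv_min <- numeric(n)
  k_per_s <- pars$k2a / 60
  for (i in 2:n) {
    w <- rep(dt, i); w[1] <- dt / 2; w[i] <- dt / 2
    conv_min[i] <- sum(w * rf01[1:i] * exp(-k_per_s * (tt[i] - tt[1:i]))) / 60
  }
  fine_oracle <- pars$R1 * rf01 + (pars$k2 - pars$R1 * pars$k2a) * conv_min
  oracle <- frame_average(fine_oracle, sched, tt)
  got <- srtm_forward(rf, pars, sched)$values
  expect_lt(max(abs(got - oracle)) / max(abs(oracle)), 1e-3)
})

test_that("phantoms carry exact forward-model kinetics per region", {
  ph <- noiseless_phantom()
  expect_equal(sort(unname(ph$labels$names)),
               sort(default_region_params()$region))

  # zero noise: all voxel TACs within a region identical, and the regional
  # mean equals the forward model output exactly
  Y <- t(matrix(ph$image$values, prod(dim(ph$labels$labels)),
                n_frames(ph$image$schedule)))
  for (r in c("thalamus", "white_matter", "precentral")) {
    m <- region_mask(ph$labels, r)
    cols <- Y[, as.vector(m)]
    expect_equal(max(apply(cols, 1, function(x) diff(range(x)))), 0)
    tr <- ph$truth[ph$truth$region == r, ]
    fwd <- srtm_forward(ph$ref_fine,
                        kinetic_params(tr$R1, tr$bp, tr$k2p),
                        ph$image$schedule)
    expect_equal(extract_tac(ph$image, m)$values, fwd$values)
  }

  # reproducibility and overlap detection
  sp <- phantom_spec(noise_scale = 0.3, seed = 5)
  expect_identical(build_phantom(sp)$image$values,
                   build_phantom(sp)$image$values)

  masks <- tspopet:::region_boxes(default_region_params()$region, c(32, 32, 16))
  masks[["thalamus"]] <- masks[["caudate"]]
  expect_error(build_phantom(phantom_spec(), masks = masks), "overlap")
})

test_that("frame-variance noise has the nominal per-frame SD", {
  sched <- frame_schedule(list(c(2, 10), c(2, 60), c(2, 300)))
  d <- c(24, 24, 24)  # 13824 voxels
  img <- dynamic_image(array(100, c(d, 6)), sched)
  expect_identical(add_noise(img, 0)$values, img$values)

  noisy <- add_noise(img, 0.5, seed = 2)
  nominal <- tspopet:::noise_frame_sd(img, 0.5)
  for (f in 1:6) {
    emp <- sd(noisy$values[, , , f] - 100)
    expect_lt(abs(emp - nominal[f]) / nominal[f], 0.05)
  }
  n2 <- add_noise(img, 0.5, seed = 3)
  expect_false(identical(noisy$values, n2$values))
  expect_equal(dim(n2$values), dim(noisy$values))
})

test_that("kinetic parameter identities hold on every generated set", {
  set.seed(21)
  for (i in 1:50) {
    p <- kinetic_params(runif(1, 0.5, 1.5), runif(1, -0.5, 3),
                        runif(1, 0.01, 0.2))
    expect_lt(abs(p$bp - (p$k2 / p$k2a - 1)), 1e-12)
    expect_lt(abs(p$k2 - p$R1 * p$k2p), 1e-12)
    expect_gt(p$k2a, 0)
  }
  expect_error(kinetic_params(-1, 0.5, 0.05), "R1")
  expect_error(kinetic_params(1, -1.5, 0.05), "bp")
})

test_that("the default cohort reproduces the study composition and outcome structure", {
  co <- simulate_cohort(seed = 4)
  expect_equal(sum(co$records$group == "control"), 24)
  expect_equal(sum(co$records$group == "anoxic"), 6)
  expect_equal(sum(co$records$group == "traumatic"), 11)
  expect_equal(nrow(co$records), 41)

  pats <- co$records$group != "control"
  expect_true(all(co$records$crs_r[pats] >= 0 & co$records$crs_r[pats] <= 23))
  expect_true(all(is.na(co$records$crs_r[!pats])))
  fav <- co$records$state %in% c("MCS", "EMCS")
  expect_equal(co$records$outcome[pats] == "favourable", fav[pats])

  # control region never incremented; anoxic regions elevated
  base <- default_region_params()
  pc_base <- base$bp[base$region == "precentral"]
  expect_lt(abs(mean(co$true_bp[, "precentral"]) - pc_base), 0.05)
  expect_gt(mean(co$true_bp[co$records$group == "anoxic", "globus_pallidum"]) -
              mean(co$true_bp[co$records$group == "control", "globus_pallidum"]),
            0.3)
  expect_gt(mean(co$true_bp[co$records$group == "traumatic", "mPFC"]) -
              mean(co$true_bp[co$records$group == "control", "mPFC"]), 0.3)

  # higher pallidal binding predicts worse recovery
  sp <- spearman_cor(co$true_bp[pats, "globus_pallidum"],
                     co$records$crs_r[pats])
  expect_lt(sp$rho, -0.4)

  # pure function of (arguments, seed)
  expect_identical(simulate_cohort(seed = 4), co)

  # zero-effect cohorts are exchangeable across groups
  null_co <- simulate_cohort(effects = cohort_effects(anoxic_lo = 0, anoxic_hi = 0,
                                                      traumatic_lo = 0,
                                                      traumatic_hi = 0),
                             seed = 8)
  expect_lt(abs(mean(null_co$true_bp[null_co$records$group == "anoxic", "thalamus"]) -
                  mean(null_co$true_bp[null_co$records$group == "control", "thalamus"])),
            0.1)

  # low-affinity binders are flagged for exclusion
  lab_co <- simulate_cohort(effects = cohort_effects(lab_fraction = 0.5), seed = 6)
  expect_true(any(lab_co$records$excluded_lab))
  expect_equal(lab_co$records$excluded_lab, lab_co$records$genotype == "LAB")
})
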