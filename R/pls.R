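#' PLS1 regression by NIPALS
#'
#' Univariate-response partial least squares: the standard NIPALS recursion
#' on column-centred X and centred y, deflating X per component. Columns are
#' centred but (by default) not variance-scaled, because voxel-wise binding
#' maps share units; set `scale = TRUE` to standardize (VIP values depend on
#' this choice).
#'
#' @param X subjects x predictors numeric matrix, no missing values
#' @param y numeric response, length nrow(X)
#' @param n_components number of latent components (>= 1, <= rank of the
#'   centred X)
#' @param scale standardize columns to unit variance
#' @return object of class `pls1_model` with weights `W`, loadings `P`,
#'   y-loadings `q`, scores `T`, centring/scaling state, per-component
#'   explained y-variance `ssy`, and total centred y sum of squares
#'   `ssy_total`
#' @export
pls1_fit <- function(X, y, n_components, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("y length must match nrow(X)")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (n_components < 1) stop("n_components must be >= 1")
  x_mean <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, stats::sd) else rep(1, p)
  if (any(x_scale == 0)) stop("cannot scale constant predictor columns")
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  yc <- y - y_mean
  rk <- qr(Xc)$rank
  if (n_components > rk)
    stop(sprintf("n_components (%d) exceeds the rank of centred X (%d)",
                 n_components, rk))
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  ssy <- numeric(n_components)
  Xd <- Xc; yd <- yc
  for (a in seq_len(n_components)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps)
      stop("deflated X carries no covariance with y; reduce n_components")
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - t_a %*% t(p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a; q[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  structure(list(W = W, P = P, q = q, T = Tm,
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 ssy = ssy, ssy_total = sum(yc^2),
                 n_components = n_components),
            class = "pls1_model")
}

#' Regression coefficients of a fitted PLS1 model
#' @param model a `pls1_model`
#' @param ncomp number of components to use (default: all fitted)
#' @return length-p coefficient vector on the original predictor scale
#' @export
pls1_coef <- function(model, ncomp = model$n_components) {
  W <- model$W[, seq_len(ncomp), drop = FALSE]
  P <- model$P[, seq_len(ncomp), drop = FALSE]
  q <- model$q[seq_len(ncomp)]
  b <- W %*% solve(crossprod(P, W), q)
  as.vector(b / model$x_scale)
}

#' @export
predict.pls1_model <- function(object, newdata,
                               ncomp = object$n_components, ...) {
  newdata <- as.matrix(newdata)
  b <- pls1_coef(object, ncomp)
  as.vector(object$y_mean +
              sweep(newdata, 2, object$x_mean) %*% b)
}

#' Variable importance in projection
#'
#' `VIP_j = sqrt(p * sum_a[ssy_a * (w_ja / ||w_a||)^2] / sum_a ssy_a)` where
#' `p` is the number of predictors and `ssy_a` the y-variance explained by
#' component a. Satisfies `mean(VIP^2) = 1`; scores above 1 flag predictors
#' with an above-average contribution to the outcome prediction.
#'
#' @param model a fitted `pls1_model`
#' @return length-p numeric vector of VIP scores
#' @export
vip_scores <- function(model) {
  if (sum(model$ssy) <= 0)
    stop("model explains no y variance; VIP undefined")
  p <- nrow(model$W)
  wn <- sweep(model$W, 2, sqrt(colSums(model$W^2)), "/")
  as.vector(sqrt(p * (wn^2 %*% model$ssy) / sum(model$ssy)))
}

#' Leave-one-out cross-validated outcome prediction
#'
#' For each held-out subject the model is refit on the remaining subjects;
#' the component count is chosen per fold by an inner leave-one-out RMSE
#' criterion, capped at `max_components`. Returns observed-vs-estimated
#' pairs.
#'
#' @param X subjects x predictors matrix
#' @param y outcome vector (length >= 3)
#' @param max_components cap on the component count (default 5)
#' @param scale standardize predictor columns
#' @return data.frame with columns observed, predicted, n_components
#' @export
loo_predict <- function(X, y, max_components = 5, scale = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 subjects")
  pred <- numeric(n); used <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
    if (stats::sd(ytr) == 0) {
      pred[i] <- ytr[1]; used[i] <- 0L
      next
    }
    amax <- min(max_components, qr(scale(Xtr, scale = FALSE))$rank)
    inner <- inner_loo_rmse(Xtr, ytr, amax, scale)
    a_star <- which.min(inner)
    fit <- pls1_fit(Xtr, ytr, a_star, scale = scale)
    pred[i] <- predict(fit, X[i, , drop = FALSE])
    used[i] <- a_star
  }
  data.frame(observed = y, predicted = pred, n_components = used)
}

# RMSE of inner leave-one-out predictions for every component count 1..amax.
# One NIPALS fit per inner fold supplies the whole component path.
inner_loo_rmse <- function(X, y, amax, scale = FALSE) {
  n <- nrow(X)
  err2 <- matrix(NA_real_, n, amax)
  for (j in seq_len(n)) {
    Xtr <- X[-j, , drop = FALSE]; ytr <- y[-j]
    if (stats::sd(ytr) == 0) { err2[j, ] <- (y[j] - ytr[1])^2; next }
    aj <- min(amax, qr(scale(Xtr, scale = FALSE))$rank)
    fit <- try(pls1_fit(Xtr, ytr, aj, scale = scale), silent = TRUE)
    if (inherits(fit, "try-error")) next
    for (a in seq_len(aj)) {
      yhat <- predict(fit, X[j, , drop = FALSE], ncomp = a)
      err2[j, a] <- (y[j] - yhat)^2
    }
    if (aj < amax) err2[j, (aj + 1):amax] <- err2[j, aj]
  }
  sqrt(colMeans(err2, na.rm = TRUE))
}

#' Reshape VIP scores into a 3D brain map
#'
#' @param vip VIP vector, one value per in-mask voxel (array order)
#' @param mask logical 3D brain mask; `sum(mask)` must equal `length(vip)`
#' @return object of class `vip_map` with 3D array `vip` and logical
#'   `important_mask` (VIP strictly greater than 1)
#' @export
vip_map <- function(vip, mask) {
  if (sum(mask) != length(vip))
    stop("VIP vector length does not match the mask size")
  m <- array(NA_real_, dim(mask))
  m[mask] <- vip
  imp <- !is.na(m) & m > 1
  structure(list(vip = m, important_mask = imp, mask = mask),
            class = "vip_map")
}

#' Stack subject bp maps into a subjects x voxels matrix
#' @param maps list of 3D arrays or `parametric_map` objects
#' @param mask logical 3D mask
#' @return matrix with one row per subject, one column per in-mask voxel
#' @export
maps_to_matrix <- function(maps, mask) {
  t(vapply(maps, function(m) {
    if (inherits(m, "parametric_map")) m <- m$bp
    as.vector(m)[as.vector(mask)]
  }, numeric(sum(mask))))
}
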