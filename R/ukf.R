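# Self-contained unscented Kalman filter for arbitrary transition and
# measurement maps (additive-noise form, scaled sigma points). The filter
# owns no model knowledge: maps are pure functions of a state vector.

#' Gaussian belief (mean and covariance)
#'
#' The filter's carried state: a mean vector and a covariance matrix. The
#' covariance is symmetrized on construction; a negative eigenvalue beyond
#' numerical tolerance is an error.
#'
#' @param mean Numeric d-vector.
#' @param cov d x d covariance matrix (scalar shorthand allowed for d = 1).
#' @return An object of class `gaussian_belief`.
#' @export
gaussian_belief <- function(mean, cov) {
  mean <- as.numeric(mean)
  if (!is.matrix(cov)) cov <- diag(as.numeric(cov), length(mean))
  if (nrow(cov) != length(mean) || ncol(cov) != length(mean))
    abort("cov must be d x d for a d-dimensional mean")
  cov <- (cov + t(cov)) / 2
  ev <- min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8 * max(1, max(abs(diag(cov)))))
    abort("covariance has a significantly negative eigenvalue")
  structure(list(mean = mean, cov = cov), class = "gaussian_belief")
}

#' @export
print.gaussian_belief <- function(x, ...) {
  cat("<gaussian_belief> d =", length(x$mean), "\n")
  cat("mean:", format(head(x$mean, 6), digits = 4),
      if (length(x$mean) > 6) "...", "\n")
  invisible(x)
}

#' UKF configuration
#'
#' Sigma-point spread hyperparameters of the scaled unscented transform and
#' the additive noise covariances. Defaults `alpha_sp = 1`, `beta_sp = 2`,
#' `kappa_sp = 0` give the plain (unscaled) symmetric sigma-point set, which
#' is unbiased on this package's oscillator models; `alpha_sp = 1e-3`
#' reproduces the narrow spread used by common packaged filters.
#'
#' @param alpha_sp Spread scale in (0, 1].
#' @param beta_sp Prior-distribution weight (2 is optimal for Gaussians).
#' @param kappa_sp Secondary scaling (usually 0).
#' @param Q_omega Process-noise covariance (matrix, or scalar variance
#'   shorthand expanded to `sigma^2 I` at run time).
#' @param Q_nu Measurement-noise covariance (same shorthand).
#' @return An object of class `ukf_config`.
#' @export
ukf_config <- function(alpha_sp = 1, beta_sp = 2, kappa_sp = 0,
                       Q_omega = NULL, Q_nu = NULL) {
  if (alpha_sp <= 0 || alpha_sp > 1) abort("alpha_sp must be in (0, 1]")
  for (Q in list(Q_omega, Q_nu)) {
    if (is.matrix(Q) && !isTRUE(all.equal(Q, t(Q))))
      abort("noise covariances must be symmetric")
  }
  structure(list(alpha_sp = alpha_sp, beta_sp = beta_sp, kappa_sp = kappa_sp,
                 Q_omega = Q_omega, Q_nu = Q_nu),
            class = "ukf_config")
}

as_cov <- function(Q, d, what) {
  if (is.null(Q)) abort(paste0(what, " covariance is not set in the config"))
  if (!is.matrix(Q)) Q <- diag(as.numeric(Q), d)
  if (nrow(Q) != d) abort(sprintf("%s covariance must be %d x %d", what, d, d))
  Q
}

# Lower-triangular Cholesky factor with escalating diagonal jitter
# (1e-12 .. 1e-6 of the mean diagonal scale). Hard error beyond max jitter.
chol_sqrt <- function(P) {
  sc <- max(1, mean(diag(P)))
  for (eps in c(0, 10^seq(-12, -6))) {
    L <- tryCatch(t(chol(P + diag(eps * sc, nrow(P)))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = eps))
  }
  abort("covariance is indefinite: Cholesky failed after maximum jitter")
}

#' Scaled sigma points of a Gaussian belief
#'
#' Generates the 2d+1 symmetric sigma points and their mean/covariance
#' weights for the scaled unscented transform. Points lie at
#' `mean +- sqrt(c) L[, i]` with `L` a Cholesky factor of the covariance and
#' `c = alpha_sp^2 (d + kappa_sp)`; the mean weights sum to 1.
#'
#' @param belief A [gaussian_belief()].
#' @param config A [ukf_config()].
#' @return A list with `points` (d x (2d+1) matrix), `wm` and `wc`
#'   (weight vectors of length 2d+1).
#' @export
ukf_sigma_points <- function(belief, config = ukf_config()) {
  d <- length(belief$mean)
  cc <- config$alpha_sp^2 * (d + config$kappa_sp)
  lambda <- cc - d
  L <- chol_sqrt(belief$cov)$L
  pts <- matrix(belief$mean, d, 2 * d + 1)
  sc <- sqrt(cc)
  pts[, 1 + seq_len(d)] <- pts[, 1 + seq_len(d)] + sc * L
  pts[, 1 + d + seq_len(d)] <- pts[, 1 + d + seq_len(d)] - sc * L
  wm <- c(lambda / cc, rep(1 / (2 * cc), 2 * d))
  wc <- wm
  wc[1] <- wc[1] + (1 - config$alpha_sp^2 + config$beta_sp)
  list(points = pts, wm = wm, wc = wc)
}

ut_moments <- function(pts, wm, wc) {
  m <- as.vector(pts %*% wm)
  D <- pts - m
  P <- D %*% (wc * t(D))
  list(mean = m, cov = (P + t(P)) / 2, dev = D)
}

#' UKF prediction step
#'
#' Propagates the sigma points through the transition map and reassembles a
#' Gaussian: predicted covariance = weighted scatter of the propagated points
#' plus the additive process covariance `Q_omega`.
#'
#' @param belief Current [gaussian_belief()].
#' @param transition Function `f(state) -> state` (vectorless, pure).
#' @param config A [ukf_config()] carrying `Q_omega`.
#' @return The predicted [gaussian_belief()].
#' @export
ukf_predict <- function(belief, transition, config) {
  sp <- ukf_sigma_points(belief, config)
  prop <- apply(sp$points, 2, transition)
  if (is.null(dim(prop))) prop <- matrix(prop, nrow = 1)
  if (!all(is.finite(prop)))
    abort("transition map produced a non-finite sigma point")
  mom <- ut_moments(prop, sp$wm, sp$wc)
  Q <- as_cov(config$Q_omega, nrow(prop), "process")
  gaussian_belief(mom$mean, mom$cov + Q)
}

#' UKF measurement update
#'
#' Standard unscented correction: sigma points are redrawn from the predicted
#' belief, pushed through the measurement map, and blended with the
#' observation through the Kalman gain built from the innovation and
#' cross-covariances. A numerically singular innovation covariance triggers a
#' warning and the update is skipped (the predicted belief is returned).
#'
#' @param predicted Predicted [gaussian_belief()].
#' @param observation Numeric observation vector.
#' @param measurement Function `h(state) -> observation-space vector`.
#' @param config A [ukf_config()] carrying `Q_nu`.
#' @return The posterior [gaussian_belief()].
#' @export
ukf_update <- function(predicted, observation, measurement, config) {
  sp <- ukf_sigma_points(predicted, config)
  Z <- apply(sp$points, 2, measurement)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  m <- nrow(Z)
  if (length(observation) != m)
    abort(sprintf("observation has length %d but the measurement map returns %d",
                  length(observation), m))
  momz <- ut_moments(Z, sp$wm, sp$wc)
  R <- as_cov(config$Q_nu, m, "measurement")
  S <- momz$cov + R
  Dx <- sp$points - predicted$mean
  Cxz <- Dx %*% (sp$wc * t(momz$dev))
  K <- tryCatch(t(solve(S, t(Cxz))), error = function(e) NULL)
  if (is.null(K)) {
    warn("singular innovation covariance: update skipped")
    return(predicted)
  }
  mean_post <- predicted$mean + as.vector(K %*% (observation - momz$mean))
  cov_post <- predicted$cov - K %*% S %*% t(K)
  gaussian_belief(mean_post, cov_post)
}

#' Run the UKF over a measurement series
#'
#' Alternates [ukf_predict()] and [ukf_update()] over the rows of a
#' measurement matrix, starting from an initial belief. Deterministic given
#' its inputs. Errors from either step are rethrown with the failing step
#' index.
#'
#' @param measurements Numeric matrix or data frame, one observation per row
#'   (a `time` column, if present, is dropped).
#' @param transition,measurement Pure state maps as in [ukf_predict()] /
#'   [ukf_update()].
#' @param init Initial [gaussian_belief()].
#' @param config A [ukf_config()] with both noise covariances set.
#' @param keep_beliefs Keep the full per-step `gaussian_belief` list
#'   (memory-heavy for long runs; default `FALSE`).
#' @return An object of class `ukf_run`: list with `mean` (n x d matrix),
#'   `sd` (n x d, square roots of the covariance diagonal), `final` (the last
#'   belief), and `beliefs` (list, when requested).
#' @export
ukf_filter <- function(measurements, transition, measurement, init,
                       config, keep_beliefs = FALSE) {
  if (is.data.frame(measurements)) {
    measurements <- as.matrix(measurements[setdiff(names(measurements), "time")])
  }
  measurements <- as.matrix(measurements)
  n <- nrow(measurements)
  if (n < 1) abort("measurements must be non-empty")
  d <- length(init$mean)
  means <- matrix(NA_real_, n, d)
  sds <- matrix(NA_real_, n, d)
  beliefs <- if (keep_beliefs) vector("list", n)
  belief <- init
  for (k in seq_len(n)) {
    belief <- tryCatch({
      pred <- ukf_predict(belief, transition, config)
      ukf_update(pred, as.numeric(measurements[k, ]), measurement, config)
    }, error = function(e) {
      abort(sprintf("filter failed at step %d: %s", k, conditionMessage(e)))
    })
    means[k, ] <- belief$mean
    sds[k, ] <- sqrt(pmax(diag(belief$cov), 0))
    if (keep_beliefs) beliefs[[k]] <- belief
  }
  structure(list(mean = means, sd = sds, final = belief, beliefs = beliefs),
            class = "ukf_run")
}

#' @export
print.ukf_run <- function(x, ...) {
  cat("<ukf_run>", nrow(x$mean), "steps, state dimension", ncol(x$mean), "\n")
  invisible(x)
}
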