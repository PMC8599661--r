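# Scaled sigma points, unscented transform, prediction-correction cycle,
# and equivalence with the analytic Kalman filter on linear-Gaussian systems.

test_that("sigma points are symmetric and their weights normalized", {
  for (cfg in list(ukf_config(), ukf_config(alpha_sp = 1e-3),
                   ukf_config(alpha_sp = 0.5, kappa_sp = 1))) {
    for (d in c(1, 3, 7)) {
      b <- gaussian_belief(seq_len(d), diag(d) + 0.1)
      sp <- ukf_sigma_points(b, cfg)
      expect_equal(ncol(sp$points), 2 * d + 1)
      # exact up to float resolution of the individual weights (which are
      # O(1/alpha^2) for small alpha)
      expect_lt(abs(sum(sp$wm) - 1), 1e-12 * max(1, max(abs(sp$wm))))
      # pairwise symmetry about the mean
      dev <- sp$points - b$mean
      expect_equal(dev[, 1 + seq_len(d), drop = FALSE],
                   -dev[, 1 + d + seq_len(d), drop = FALSE])
    }
  }
  # d = 1: three points {0, +c, -c}
  sp1 <- ukf_sigma_points(gaussian_belief(0, 1), ukf_config())
  expect_equal(as.numeric(sp1$points[1]), 0)
  expect_gt(sp1$points[2], 0)
  expect_equal(sp1$points[3], -sp1$points[2])
})

test_that("the unscented transform is exact for the identity map", {
  cfg <- ukf_config()
  b <- gaussian_belief(c(1, -2, 0.5), crossprod(matrix(rnorm(9), 3)) + diag(3))
  sp <- ukf_sigma_points(b, cfg)
  m <- as.vector(sp$points %*% sp$wm)
  dev <- sp$points - m
  P <- dev %*% (sp$wc * t(dev))
  expect_equal(m, b$mean, tolerance = 1e-10)
  expect_equal(P, b$cov, tolerance = 1e-10)
})

test_that("prediction reproduces the linear-Gaussian closed form", {
  cfg0 <- ukf_config(Q_omega = matrix(0, 2, 2))
  b <- gaussian_belief(c(0.3, -1), matrix(c(2, 0.5, 0.5, 1), 2))
  # identity map with zero process noise leaves the belief unchanged
  pred <- ukf_predict(b, identity, cfg0)
  expect_equal(pred$mean, b$mean, tolerance = 1e-10)
  expect_equal(pred$cov, b$cov, tolerance = 1e-10)
  # linear map M: mean -> M mu, cov -> M P M' + Q
  M <- matrix(c(0.9, 0.2, -0.1, 1.1), 2)
  Q <- diag(c(0.1, 0.2))
  cfgQ <- ukf_config(Q_omega = Q)
  pred <- ukf_predict(b, function(u) as.vector(M %*% u), cfgQ)
  expect_equal(pred$mean, as.vector(M %*% b$mean), tolerance = 1e-8)
  expect_equal(pred$cov, M %*% b$cov %*% t(M) + Q, tolerance = 1e-8)
  expect_symmetric_psd(pred$cov)
})

test_that("update behaves correctly in the limiting cases", {
  P <- matrix(c(1, 0.3, 0.3, 2), 2)
  pred <- gaussian_belief(c(1, 2), P)
  # near-exact full-state observation dominates the prior
  cfg <- ukf_config(Q_nu = diag(1e-12, 2))
  post <- ukf_update(pred, c(0.5, -0.5), identity, cfg)
  expect_equal(post$mean, c(0.5, -0.5), tolerance = 1e-4)
  # observation equal to the predicted measurement mean: no correction
  cfg2 <- ukf_config(Q_nu = diag(0.5, 2))
  post2 <- ukf_update(pred, c(1, 2), identity, cfg2)
  expect_equal(post2$mean, pred$mean, tolerance = 1e-10)
  # posterior is never less certain than the prediction (identity map, PD R)
  expect_lte(sum(diag(post2$cov)), sum(diag(pred$cov)))
})

test_that("dimension mismatches and indefinite covariances are reported", {
  pred <- gaussian_belief(c(1, 2), diag(2))
  cfg <- ukf_config(Q_nu = diag(0.1, 1))
  expect_error(ukf_update(pred, c(1, 2), function(u) u[1], cfg), "length")
  bad <- structure(list(mean = 0, cov = matrix(-1, 1, 1)),
                   class = "gaussian_belief")
  expect_error(ukf_sigma_points(bad, ukf_config()), "jitter|indefinite")
})

test_that("the UKF matches the analytic Kalman filter on a linear system", {
  Fm <- matrix(c(1, 0, 0.1, 0.9), 2)
  H <- matrix(c(1, 0), 1)
  Q <- diag(c(0.01, 0.02))
  R <- matrix(0.25)
  m0 <- c(0, 1)
  P0 <- diag(2)
  set.seed(42)
  n <- 60
  x <- c(0, 1)
  zs <- matrix(NA_real_, n, 1)
  xs <- matrix(NA_real_, n, 2)
  for (k in seq_len(n)) {
    x <- as.vector(Fm %*% x) + rnorm(2, 0, sqrt(diag(Q)))
    xs[k, ] <- x
    zs[k, 1] <- x[1] + rnorm(1, 0, 0.5)
  }
  oracle <- kf_linear(zs, Fm, H, Q, R, m0, P0)
  for (cfg in list(ukf_config(Q_omega = Q, Q_nu = R),
                   ukf_config(alpha_sp = 1e-3, Q_omega = Q, Q_nu = R))) {
    run <- ukf_filter(zs, function(u) as.vector(Fm %*% u),
                      function(u) u[1], gaussian_belief(m0, P0), cfg,
                      keep_beliefs = TRUE)
    expect_equal(run$mean, oracle$mean, tolerance = 1e-6)
    for (k in c(1, 10, n)) {
      expect_equal(run$beliefs[[k]]$cov, oracle$cov[[k]], tolerance = 1e-6)
      expect_symmetric_psd(run$beliefs[[k]]$cov)
    }
  }
  # filtering beats the raw measurements on the observed component
  run <- ukf_filter(zs, function(u) as.vector(Fm %*% u), function(u) u[1],
                    gaussian_belief(m0, P0), ukf_config(Q_omega = Q, Q_nu = R))
  rmse_filt <- sqrt(mean((run$mean[, 1] - xs[, 1])^2))
  rmse_raw <- sqrt(mean((zs[, 1] - xs[, 1])^2))
  expect_lt(rmse_filt, rmse_raw)
})

test_that("the filter emits one belief per measurement and is deterministic", {
  cfg <- ukf_config(Q_omega = diag(0.1, 1), Q_nu = diag(0.5, 1))
  zs <- matrix(sin(seq_len(17) / 3), 17, 1)
  run <- ukf_filter(zs, function(u) 0.9 * u, identity,
                    gaussian_belief(0, 1), cfg)
  expect_equal(nrow(run$mean), 17)
  run2 <- ukf_filter(zs, function(u) 0.9 * u, identity,
                     gaussian_belief(0, 1), cfg)
  expect_identical(run$mean, run2$mean)
  expect_error(ukf_filter(zs[0, , drop = FALSE], identity, identity,
                          gaussian_belief(0, 1), cfg), "non-empty")
})

test_that("permuting state components permutes the belief sequence", {
  Fm <- matrix(c(1, 0, 0.1, 0.9), 2)
  Q <- diag(c(0.01, 0.02))
  R <- matrix(0.25)
  set.seed(7)
  zs <- matrix(rnorm(30), 30, 1)
  Pm <- matrix(c(0, 1, 1, 0), 2)  # swap the two components
  cfg1 <- ukf_config(Q_omega = Q, Q_nu = R)
  cfg2 <- ukf_config(Q_omega = Pm %*% Q %*% t(Pm), Q_nu = R)
  run1 <- ukf_filter(zs, function(u) as.vector(Fm %*% u), function(u) u[1],
                     gaussian_belief(c(0, 1), diag(c(1, 2))), cfg1)
  run2 <- ukf_filter(zs,
                     function(u) as.vector(Pm %*% Fm %*% t(Pm) %*% u),
                     function(u) u[2],
                     gaussian_belief(c(1, 0), diag(c(2, 1))), cfg2)
  expect_equal(run1$mean, run2$mean[, c(2, 1)], tolerance = 1e-9)
})
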