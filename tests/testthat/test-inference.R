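# Augmented-state estimation: extended covariance and transition, coupling
# recovery on two-node motifs, hidden-state recovery for a single node.

test_that("noise covariance estimates match the sampling distribution", {
  expect_equal(estimate_noise_covariance(0, 4), matrix(0, 4, 4))
  Q <- estimate_noise_covariance(0.02, 6, n_samples = 100000, seed = 2)
  expect_identical(Q, t(Q))
  expect_equal(diag(Q), rep(4e-4, 6), tolerance = 0.05)
  # off-diagonals: zero within 3 standard errors (SE ~ sigma^2 / sqrt(n))
  off <- Q[upper.tri(Q)]
  expect_lt(max(abs(off)), 3 * 4e-4 / sqrt(100000) * 1.5)
})

test_that("extended covariance zeroes the parameter block exactly", {
  Qw <- estimate_noise_covariance(0.02, 6, n_samples = 5000, seed = 1)
  Qe <- build_extended_covariance(Qw, 1)
  expect_equal(dim(Qe), c(7, 7))
  expect_identical(Qe[7, ], rep(0, 7))
  expect_identical(Qe[, 7], rep(0, 7))
  expect_identical(Qe[1:6, 1:6], Qw)
  expect_identical(build_extended_covariance(Qw, 0), Qw)
  Qbig <- build_extended_covariance(diag(84), 378)
  expect_equal(dim(Qbig), c(462, 462))
  expect_true(all(Qbig[85:462, ] == 0) && all(Qbig[, 85:462] == 0))
})

test_that("extended transition freezes parameters and matches the model step", {
  p <- oscillator_params()
  g <- sampling_grid(37000, 10)
  net <- two_node_net(0.37)
  f <- make_extended_transition(p, net, g, mode = "single_k")
  u <- c(runif(6, -1, 1), 0.37)
  out <- f(u)
  expect_identical(out[7], u[7])
  # frozen at the true K: dynamical substate equals the plain RK4 advance
  expect_equal(out[1:6], rk4_step(u[1:6], g$dt, p, net))
  # all-pairs mode with all couplings zero: nodes advance uncoupled
  A0 <- matrix(0, 3, 3)
  f3 <- make_extended_transition(p, network_model(A0), sampling_grid(37000, 10),
                                 mode = "all_pairs")
  u3 <- c(runif(9, -1, 1), rep(0, 3))
  out3 <- f3(u3)
  for (i in 1:3) {
    cols <- (3 * i - 2):(3 * i)
    expect_equal(out3[cols],
                 rk4_step(u3[cols], g$dt, p, network_model(n_nodes = 1)))
  }
  expect_identical(out3[10:12], rep(0, 3))
})

test_that("two-node coupling strength is recovered from y-only data", {
  dat <- cached("n2_K01_n20000", two_node_data(0.1, 20000, seed = 101))
  fit <- cached("fit_K01", estimate_coupling(
    dat$measurements, mode = "single_k", net = dat$net, seed = 101))
  expect_s3_class(fit, "coupling_fit")
  expect_identical(fit$terms, "K")
  final <- fit$estimate[fit$n_steps, 1]
  expect_lt(abs(final - 0.1), 0.05)
  # the one-sigma band is positive and shrinks as data accumulate
  expect_true(all(fit$sd >= 0))
  expect_lt(fit$sd[fit$n_steps, 1], fit$sd[100, 1])
  # tidy/glance accessors agree with the stored matrices
  td <- tidy(fit)
  expect_named(td, c("step", "time", "term", "estimate", "sd"))
  expect_equal(nrow(td), fit$n_steps)
  expect_equal(td$estimate[td$step == fit$n_steps], final)
  expect_equal(glance(fit)$n_parameters, 1L)
})

test_that("directional couplings of a symmetric pair are both recovered", {
  dat <- cached("n2_K01_n20000", two_node_data(0.1, 20000, seed = 101))
  fit <- estimate_coupling(dat$measurements, mode = "directional_pair",
                           seed = 101)
  expect_identical(fit$terms, c("K12", "K21"))
  sm <- summarize_trace(fit)
  # symmetric truth: the two estimates agree within their +-1 sigma bands
  fin <- fit$estimate[fit$n_steps, ]
  sds <- fit$sd[fit$n_steps, ]
  expect_lt(abs(fin[1] - fin[2]), sds[1] + sds[2])
  expect_true(all(abs(sm$median - 0.1) < 0.1))
})

test_that("estimation is robust to conservatively misspecified filter noise", {
  dat <- cached("n2_K04_n20000", two_node_data(0.4, 20000, seed = 31))
  for (ns in list(noise_spec(0.001, 0.5), noise_spec(0.001, 1),
                  noise_spec(0.02, 1))) {
    fit <- estimate_coupling(dat$measurements, mode = "single_k",
                             net = dat$net, noise = ns, seed = 31)
    expect_lt(abs(summarize_trace(fit)$median - 0.4), 0.1)
  }
})

test_that("hidden x and z are recovered from noisy y alone", {
  dat1 <- cached("n1_n20000", {
    net <- network_model(n_nodes = 1)
    tr <- simulate_oscillators(net, sampling = sampling_grid(37000, 20000),
                               discard = 20000, seed = 3)
    list(trajectory = tr, measurements = measure_trajectory(tr))
  })
  sf <- cached("statefit_y", recover_hidden_states(dat1$measurements, seed = 3))
  tr <- dat1$trajectory
  expect_gt(cor(sf$states$x, tr$x1), 0.95)
  expect_gt(cor(sf$states$z, tr$z1), 0.95)
  # filtering beats the raw observation of y (reference: measurement-noise
  # free simulated y)
  rmse_filt <- sqrt(mean((sf$states$y - tr$y1)^2))
  rmse_raw <- sqrt(mean((dat1$measurements$y1 - tr$y1)^2))
  expect_lt(rmse_filt, rmse_raw)
  expect_lt(rmse_filt, 0.5)
})

test_that("observing x instead of y recovers the other two variables", {
  dat1 <- cached("n1_n20000", {
    net <- network_model(n_nodes = 1)
    tr <- simulate_oscillators(net, sampling = sampling_grid(37000, 20000),
                               discard = 20000, seed = 3)
    list(trajectory = tr, measurements = measure_trajectory(tr))
  })
  msx <- measure_trajectory(dat1$trajectory, observe = "x")
  sfx <- recover_hidden_states(msx, seed = 3)
  expect_identical(sfx$observe, "x")
  expect_gt(cor(sfx$states$y, dat1$trajectory$y1), 0.95)
  expect_gt(cor(sfx$states$z, dat1$trajectory$z1), 0.95)
})

test_that("mode/shape inconsistencies are rejected", {
  dat <- cached("n2_K01_n20000", two_node_data(0.1, 20000, seed = 101))
  expect_error(estimate_coupling(dat$measurements, mode = "single_k"),
               "adjacency")
  ms3 <- dat$measurements
  ms3$y3 <- ms3$y1
  expect_error(estimate_coupling(ms3, mode = "directional_pair", seed = 1),
               "N = 2")
  expect_error(recover_hidden_states(dat$measurements, seed = 1),
               "single-oscillator")
})
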