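# Oscillator model, RK4 integrator, stochastic simulator, measurement map.

test_that("switching nonlinearity has the right branches and is continuous", {
  expect_equal(g_nonlinearity(2.0, v_th = 3.0088, mu = 15), 0)
  expect_equal(g_nonlinearity(3.0088, v_th = 3.0088, mu = 15), 0)
  expect_equal(g_nonlinearity(4.0088, v_th = 3.0088, mu = 15), 15)
  # continuity at the threshold
  eps <- 1e-12
  expect_lt(abs(g_nonlinearity(3.0088 + eps, 3.0088, 15)), 1e-9)
  # vectorized
  expect_equal(g_nonlinearity(c(0, 10), 3.0088, 15), c(0, 15 * (10 - 3.0088)))
})

test_that("drift reproduces the model equations", {
  p <- oscillator_params()
  net1 <- network_model(n_nodes = 1)
  # direct evaluation oracle at state (x, y, z) = (0, 1, 0):
  # xdot = -alpha1 * beta * y, ydot = -alpha2 * (1 - delta) * y, zdot = 0
  expect_equal(drift(c(0, 1, 0), p, net1),
               c(-p$alpha1 * p$beta, -p$alpha2 * (1 - p$delta), 0))
  # origin is a fixed point for any N and K
  for (N in c(1, 3)) {
    net <- if (N == 1) network_model(n_nodes = 1) else
      random_network(N, edge_density = 1, K = 0.7, seed = 1)
    expect_equal(drift(rep(0, 3 * N), p, net), rep(0, 3 * N))
  }
  expect_equal(drift(rep(0, 3), oscillator_params("n28"),
                     network_model(n_nodes = 1)), rep(0, 3))
})

test_that("coupling vanishes when all y are equal and only neighbours enter", {
  p <- oscillator_params()
  s1 <- c(0.3, -0.2, 0.05)
  net2 <- two_node_net(0.83)
  d2 <- drift(c(s1, s1), p, net2)
  d1 <- drift(s1, p, network_model(n_nodes = 1))
  expect_equal(d2, c(d1, d1))
  # node 3 disconnected from 1-2: its derivative matches the uncoupled one
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  net3 <- network_model(A, K = 0.5)
  s3 <- c(0.3, -0.2, 0.05, 0.1, 0.8, 0, -0.4, 0.2, 0.1)
  d3 <- drift(s3, p, net3)
  expect_equal(d3[7:9], drift(s3[7:9], p, network_model(n_nodes = 1)))
})

test_that("RK4 is deterministic and fourth-order on the exponential problem", {
  f <- function(u) -u
  # closed-form oracle: u(dt) = exp(-dt)
  err <- function(dt) abs(rk4_step(1, dt, drift_fn = f) - exp(-dt))
  expect_gt(err(0.1) / err(0.05), 2^4)
  expect_gt(err(0.05) / err(0.025), 2^4)
  # determinism and fixed-point preservation for the oscillator map
  p <- oscillator_params()
  net <- two_node_net(0.4)
  s <- runif(6, -1, 1)
  expect_identical(rk4_step(s, 1 / 37000, p, net),
                   rk4_step(s, 1 / 37000, p, net))
  expect_equal(rk4_step(rep(0, 6), 1 / 37000, p, net), rep(0, 6))
})

test_that("model RK4 agrees with an independent ODE integrator", {
  skip_if_not_installed("deSolve")
  p <- oscillator_params()
  net <- two_node_net(0.6)
  s0 <- c(0.05, -0.02, 0.01, -0.03, 0.04, 0)
  n <- 200
  dt <- 1 / 37000
  u <- s0
  for (k in seq_len(n)) u <- rk4_step(u, dt, p, net)
  sol <- deSolve::ode(
    y = s0, times = c(0, n * dt),
    parms = NULL,
    func = function(t, y, parms) list(drift(y, p, net)),
    method = "ode45", rtol = 1e-10, atol = 1e-12)
  # tolerance reflects RK4's own accumulated truncation error at dt = 1/f_s
  # (alpha3 * dt ~ 0.27, so the local error is ~1e-5 per step)
  expect_equal(u, as.numeric(sol[2, -1]), tolerance = 2e-3)
})

test_that("simulation is seed-reproducible and symmetric for identical nodes", {
  net <- two_node_net(0)
  g <- sampling_grid(37000, 500)
  init <- rep(c(0.05, -0.02, 0.01), 2)
  t1 <- simulate_oscillators(net, sampling = g, init = init, seed = 4)
  t2 <- simulate_oscillators(net, sampling = g, init = init, seed = 4)
  expect_identical(t1, t2)
  # K = 0, zero process noise, identical initial nodes => identical paths
  t3 <- simulate_oscillators(net, sampling = g, init = init,
                             noise = noise_spec(0, 0.5), seed = 4)
  expect_equal(t3[c("x1", "y1", "z1")], setNames(t3[c("x2", "y2", "z2")],
                                                 c("x1", "y1", "z1")))
})

test_that("process noise magnitude matches sigma_omega", {
  net <- network_model(n_nodes = 1)
  n <- 20000
  tr <- simulate_oscillators(net, sampling = sampling_grid(37000, n),
                             noise = noise_spec(0.02, 0.5), seed = 9)
  states <- as.matrix(tr[c("x1", "y1", "z1")])
  p <- oscillator_params()
  # injected noise = state[k+1] - rk4(state[k]); sample its std
  idx <- seq_len(n - 1)
  pred <- t(vapply(idx, function(k)
    rk4_step(states[k, ], 1 / 37000, p, net), numeric(3)))
  resid <- states[idx + 1, ] - pred
  expect_equal(sd(as.vector(resid)), 0.02, tolerance = 0.02)
})

test_that("an uncoupled network decouples into independent single nodes", {
  p <- oscillator_params()
  dt <- 1 / 37000
  n <- 300
  set.seed(11)
  noise <- matrix(rnorm((n - 1) * 9, 0, 0.02), n - 1, 9)
  init <- runif(9, -0.1, 0.1)
  full <- ukfnet:::.cpp_simulate(init, n, dt, unclass(p), matrix(0, 3, 3),
                                 noise)
  for (i in 1:3) {
    cols <- (3 * i - 2):(3 * i)
    single <- ukfnet:::.cpp_simulate(init[cols], n, dt, unclass(p),
                                     matrix(0, 1, 1),
                                     noise[, cols, drop = FALSE])
    expect_equal(full[, cols], single)
  }
})

test_that("noise-free single-node dynamics stay bounded and non-periodic", {
  net <- network_model(n_nodes = 1)
  tr <- simulate_oscillators(net, sampling = sampling_grid(37000, 100000),
                             noise = noise_spec(0, 0), seed = 5)
  states <- as.matrix(tr[c("x1", "y1", "z1")])
  expect_lt(max(abs(states)), 50)
  # no exact state recurrence after the initial point
  expect_false(any(duplicated(states)))
  # actually oscillating, not collapsed to a fixed point
  expect_gt(sd(states[, 2]), 0.5)
})

test_that("simulation reports blow-up with the failing step", {
  net <- network_model(n_nodes = 1)
  # unstable parameterization: positive feedback with no saturation
  bad <- oscillator_params(mu = 0, delta = 50)
  expect_error(
    simulate_oscillators(net, params = bad,
                         sampling = sampling_grid(37000, 100000),
                         noise = noise_spec(0, 0), init = c(1, 1, 1)),
    "step")
})

test_that("measurement map extracts the observed column and adds sigma_nu noise", {
  dat <- cached("n2_K01_n6000", two_node_data(0.1, 6000, seed = 301))
  tr <- dat$trajectory
  clean <- measure_trajectory(tr, noise = noise_spec(0.02, 0), seed = 1)
  expect_named(clean, c("time", "y1", "y2"))
  expect_equal(clean$y1, tr$y1)
  expect_equal(clean$y2, tr$y2)
  noisy <- measure_trajectory(tr, noise = noise_spec(0.02, 0.5), seed = 1)
  resid <- c(noisy$y1 - tr$y1, noisy$y2 - tr$y2)
  expect_equal(sd(resid), 0.5, tolerance = 0.02)
  expect_equal(mean(resid), 0, tolerance = 0.02)
  # x can be observed instead of y
  xs <- measure_trajectory(tr, noise = noise_spec(0.02, 0), observe = "x")
  expect_named(xs, c("time", "x1", "x2"))
  expect_equal(xs$x1, tr$x1)
})

test_that("random networks honour the edge budget, symmetry and the seed", {
  n1 <- random_network(2, n_edges = 1, seed = 1)
  expect_equal(n1$A, matrix(c(0, 1, 1, 0), 2))
  n28 <- random_network(28, edge_density = 0.2, seed = 3)
  expect_equal(dim(n28$A), c(28, 28))
  expect_equal(n28$A, t(n28$A))
  expect_equal(diag(n28$A), rep(0, 28))
  expect_identical(n28$A, random_network(28, edge_density = 0.2, seed = 3)$A)
  expect_false(identical(n28$A,
                         random_network(28, edge_density = 0.2, seed = 4)$A))
  expect_error(random_network(4, n_edges = 10), "possible")
})

test_that("sampling grid derives dt from the rate", {
  g <- sampling_grid(37000, 10)
  expect_identical(g$dt * g$f_s, 1)
  expect_error(sampling_grid(37000, 0), "n_steps")
})
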