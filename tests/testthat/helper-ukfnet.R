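# Shared fixtures and independent oracles, all built in code at test time.

two_node_net <- function(K) network_model(matrix(c(0, 1, 1, 0), 2), K = K)

# Simulated two-node data set on the attractor (transient discarded).
two_node_data <- function(K, n_steps, seed, preset = "n1_2") {
  net <- two_node_net(K)
  tr <- simulate_oscillators(
    net, params = oscillator_params(preset),
    sampling = sampling_grid(preset_f_s(preset), n_steps),
    noise = noise_spec(preset = preset), discard = 20000, seed = seed)
  list(net = net, trajectory = tr, measurements = measure_trajectory(tr))
}

preset_f_s <- function(preset) if (preset == "n28") 30000 else 37000

# Cache expensive fits so several test files can share one run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (exists(key, .fixture_cache)) {
    v <- get(key, .fixture_cache)
    if (!is.null(v)) return(v)
  }
  v <- force(expr)
  if (!is.null(v)) assign(key, v, .fixture_cache)
  v
}

# Textbook linear Kalman filter recursion (the analytic oracle the UKF must
# match on linear-Gaussian systems).
kf_linear <- function(zs, Fm, H, Q, R, m0, P0) {
  n <- nrow(zs)
  d <- length(m0)
  means <- matrix(NA_real_, n, d)
  covs <- vector("list", n)
  m <- m0
  P <- P0
  for (k in seq_len(n)) {
    m <- as.vector(Fm %*% m)
    P <- Fm %*% P %*% t(Fm) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    m <- m + as.vector(K %*% (zs[k, ] - H %*% m))
    P <- P - K %*% H %*% P
    means[k, ] <- m
    covs[[k]] <- P
  }
  list(mean = means, cov = covs)
}

expect_symmetric_psd <- function(P, tol_sym = 1e-9, tol_eig = 1e-8) {
  expect_lt(max(abs(P - t(P))), tol_sym)
  expect_gt(min(eigen((P + t(P)) / 2, symmetric = TRUE,
                      only.values = TRUE)$values), -tol_eig)
}
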