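# Joint state-parameter estimation: the state vector is augmented with the
# unknown coupling parameters (constant dynamics, zero process noise) and the
# UKF estimates state and couplings jointly from y-only measurements.

#' Sample covariance of a synthetic noise realization
#'
#' The filter's noise covariances are estimated from realizations of the
#' corresponding Gaussian processes rather than prescribed analytically:
#' this returns the sample covariance of `n_samples` i.i.d. draws from
#' `N(0, sigma^2 I_dim)`.
#'
#' @param sigma Noise standard deviation (>= 0).
#' @param dim Dimension of the noise vector.
#' @param n_samples Number of realizations (>= 2; default 1e5).
#' @param seed Seed for the realization.
#' @return A symmetric `dim` x `dim` matrix (exactly zero when `sigma = 0`).
#' @export
estimate_noise_covariance <- function(sigma, dim, n_samples = 100000,
                                      seed = NULL) {
  stopifnot(sigma >= 0, dim >= 1, n_samples >= 2)
  if (sigma == 0) return(matrix(0, dim, dim))
  draws <- with_seed(seed, matrix(rnorm(n_samples * dim, 0, sigma),
                                  n_samples, dim))
  Q <- cov(draws)
  (Q + t(Q)) / 2
}

#' Extended process covariance for augmented parameters
#'
#' Builds the (n+q) x (n+q) process covariance of the augmented state: the
#' top-left block is the dynamical-state covariance `Q_omega`, and all rows
#' and columns belonging to the q constant parameters are exactly zero (the
#' parameters evolve without process noise).
#'
#' @param Q_omega Square symmetric process covariance of the dynamical state.
#' @param q Number of augmented parameters (>= 0).
#' @return The extended covariance matrix.
#' @export
build_extended_covariance <- function(Q_omega, q) {
  Q_omega <- as.matrix(Q_omega)
  if (nrow(Q_omega) != ncol(Q_omega)) abort("Q_omega must be square")
  if (!isTRUE(all.equal(Q_omega, t(Q_omega))))
    abort("Q_omega must be symmetric")
  if (q == 0) return(Q_omega)
  n <- nrow(Q_omega)
  Qe <- matrix(0, n + q, n + q)
  Qe[seq_len(n), seq_len(n)] <- Q_omega
  Qe
}

# Mapping from estimation mode to the parameter layout: cidx[i,j] = r > 0
# means the coupling weight W[i,j] is the r-th augmented parameter; 0 means
# the known value B[i,j] is used.
coupling_layout <- function(mode, n_nodes, net = NULL) {
  cidx <- matrix(0L, n_nodes, n_nodes)
  B <- matrix(0, n_nodes, n_nodes)
  if (mode == "single_k") {
    if (is.null(net)) abort("single_k mode needs the known adjacency (net)")
    if (net$n_nodes != n_nodes)
      abort("network size does not match the measurement columns")
    cidx[net$A == 1] <- 1L
    labels <- "K"
    q <- 1L
  } else if (mode == "directional_pair") {
    if (n_nodes != 2) abort("directional_pair mode requires N = 2")
    cidx[1, 2] <- 1L
    cidx[2, 1] <- 2L
    labels <- c("K12", "K21")
    q <- 2L
  } else if (mode == "all_pairs") {
    if (n_nodes < 2) abort("all_pairs mode requires N >= 2")
    q <- 0L
    labels <- character(0)
    for (i in seq_len(n_nodes - 1)) {
      for (j in seq(i + 1, n_nodes)) {
        q <- q + 1L
        cidx[i, j] <- q
        cidx[j, i] <- q
        labels <- c(labels, sprintf("K%d_%d", i, j))
      }
    }
  } else {
    abort(paste0("unknown mode: ", mode))
  }
  list(cidx = cidx, B = B, q = q, labels = labels)
}

#' Transition map on the augmented state
#'
#' Returns a pure function on the (3N+q)-dimensional augmented state: the
#' dynamical substate advances by one RK4 step using the coupling values read
#' from the parameter substate, and the parameter substate is copied
#' unchanged (constant dynamics, `dp/dt = 0`).
#'
#' @param params [oscillator_params()].
#' @param net Network template; supplies the known adjacency in `single_k`
#'   mode and the node count otherwise.
#' @param sampling [sampling_grid()] (only `dt` is used).
#' @param mode One of `"single_k"`, `"directional_pair"`, `"all_pairs"`.
#' @return A function mapping a (3N+q)-vector to a (3N+q)-vector.
#' @export
make_extended_transition <- function(params, net, sampling,
                                     mode = c("single_k", "directional_pair",
                                              "all_pairs")) {
  mode <- match.arg(mode)
  N <- net$n_nodes
  lay <- coupling_layout(mode, N, net)
  dt <- sampling$dt
  p <- unclass(params)
  function(u) {
    stopifnot(length(u) == 3 * N + lay$q)
    pvals <- u[seq(3 * N + 1, length.out = lay$q)]
    W <- lay$B
    sel <- lay$cidx > 0
    W[sel] <- pvals[lay$cidx[sel]]
    c(as.vector(.cpp_rk4_step(u[seq_len(3 * N)], dt, p, W)), pvals)
  }
}

obs_indices0 <- function(observe, n_nodes) {
  off <- match(observe, c("x", "y", "z")) - 1L
  as.integer(3 * (seq_len(n_nodes) - 1) + off)
}

meas_matrix <- function(measurements) {
  if (is.data.frame(measurements)) {
    tm <- measurements$time
    m <- as.matrix(measurements[setdiff(names(measurements), "time")])
  } else {
    tm <- NULL
    m <- as.matrix(measurements)
  }
  list(values = m, time = tm)
}

resolve_dt <- function(measurements, sampling) {
  if (!is.null(sampling)) return(sampling$dt)
  sa <- attr(measurements, "sampling")
  if (!is.null(sa)) return(sa$dt)
  if (is.data.frame(measurements) && "time" %in% names(measurements) &&
      nrow(measurements) > 1)
    return(diff(measurements$time[1:2]))
  abort("cannot determine dt: supply a sampling_grid")
}

#' Estimate coupling parameters from y-only measurements
#'
#' Runs the UKF on the parameter-augmented oscillator model to estimate,
#' depending on `mode`: the global coupling strength `K` with a known
#' adjacency matrix (`"single_k"`), the two directed couplings `K12`, `K21`
#' of a two-node motif (`"directional_pair"`), or all `N(N-1)/2` pairwise
#' couplings `K * A[i, j]` of a symmetric network (`"all_pairs"`). The
#' filter's process and measurement covariances are estimated from
#' realizations of Gaussian noise with the standard deviations in `noise`
#' (see [estimate_noise_covariance()]); the parameter rows of the extended
#' process covariance are exactly zero.
#'
#' The initial filter state puts each `y_i` at its first measurement and
#' `x_i`, `z_i` at zero; parameters start at `init_guess` with variance
#' `init_param_var`. Estimates are unconstrained (they may transiently leave
#' `[0, 1]`).
#'
#' @param measurements Tibble from [measure_trajectory()] (columns `time`,
#'   `y1 ... yN`) or an equivalent matrix.
#' @param mode Estimation mode (see above).
#' @param net Known network; required in `"single_k"` mode, otherwise used
#'   only for the node count (inferred from the columns when omitted).
#' @param params [oscillator_params()].
#' @param noise [noise_spec()] with the standard deviations assumed by the
#'   filter (defaults to the measurement series' own attribute).
#' @param sampling Optional [sampling_grid()]; inferred from the
#'   measurements when omitted.
#' @param config [ukf_config()]; matrix noise covariances set there override
#'   the realization-based estimates.
#' @param init_guess Initial value of every coupling parameter (default 0.5,
#'   the midpoint of the `[0, 1]` experimental range).
#' @param init_state_var,init_param_var Initial diagonal variances of the
#'   dynamical and parameter blocks (defaults 1 and 0.25).
#' @param n_cov_samples Realization length for the covariance estimates.
#' @param seed Master seed (split into independent streams for the two
#'   covariance realizations).
#' @return An object of class `coupling_fit`; see [tidy.coupling_fit()],
#'   [glance.coupling_fit()], [summarize_trace()], [autoplot.coupling_fit()].
#' @examples
#' \donttest{
#' net <- network_model(matrix(c(0, 1, 1, 0), 2), K = 0.1)
#' tr <- simulate_oscillators(net, sampling = sampling_grid(n_steps = 4000),
#'                            discard = 20000, seed = 7)
#' ms <- measure_trajectory(tr)
#' fit <- estimate_coupling(ms, mode = "single_k", net = net, seed = 7)
#' glance(fit)
#' }
#' @export
estimate_coupling <- function(measurements,
                              mode = c("single_k", "directional_pair",
                                       "all_pairs"),
                              net = NULL, params = oscillator_params(),
                              noise = NULL, sampling = NULL,
                              config = ukf_config(), init_guess = 0.5,
                              init_state_var = 1, init_param_var = 0.25,
                              n_cov_samples = 100000, seed = NULL) {
  mode <- match.arg(mode)
  mm <- meas_matrix(measurements)
  N <- ncol(mm$values)
  n <- nrow(mm$values)
  if (is.null(net) && mode != "single_k") net <- network_model(n_nodes = N)
  lay <- coupling_layout(mode, N, net)
  dt <- resolve_dt(measurements, sampling)
  if (is.null(noise)) noise <- attr(measurements, "noise")
  if (is.null(noise) && (!is.matrix(config$Q_omega) || !is.matrix(config$Q_nu)))
    abort("supply a noise_spec (or matrix covariances in the config)")
  seeds <- split_seed(seed, c("q_omega", "q_nu"))
  Qw <- if (is.matrix(config$Q_omega)) config$Q_omega else
    estimate_noise_covariance(noise$sigma_omega, 3 * N, n_cov_samples,
                              seeds$q_omega)
  Qnu <- if (is.matrix(config$Q_nu)) config$Q_nu else
    estimate_noise_covariance(noise$sigma_nu, N, n_cov_samples, seeds$q_nu)
  Qe <- build_extended_covariance(Qw, lay$q)
  d <- 3 * N + lay$q
  m0 <- numeric(d)
  m0[3 * (seq_len(N) - 1) + 2] <- mm$values[1, ]
  m0[seq(3 * N + 1, length.out = lay$q)] <- init_guess
  P0 <- diag(c(rep(init_state_var, 3 * N), rep(init_param_var, lay$q)))
  res <- .cpp_ukf_model(mm$values, obs_indices0("y", N), dt, unclass(params),
                        lay$cidx, lay$B, lay$q, Qe, Qnu, m0, P0,
                        config$alpha_sp, config$beta_sp, config$kappa_sp)
  pcols <- seq(3 * N + 1, length.out = lay$q)
  time <- if (!is.null(mm$time)) mm$time else (seq_len(n) - 1) * dt
  structure(list(
    estimate = res$mean[, pcols, drop = FALSE],
    sd = res$sd[, pcols, drop = FALSE],
    state_mean = res$mean[n, seq_len(3 * N)],
    final_cov = res$final_cov,
    terms = lay$labels, mode = mode, n_nodes = N, n_steps = n, time = time,
    dt = dt, jitter_events = res$jitter_events,
    skipped_updates = res$skipped_updates,
    config = config, init_guess = init_guess, seed = seed
  ), class = "coupling_fit")
}

#' @export
print.coupling_fit <- function(x, ...) {
  cat("<coupling_fit>", x$mode, "mode:", length(x$terms),
      "parameter(s) over", x$n_steps, "steps\n")
  fin <- x$estimate[x$n_steps, ]
  show <- head(seq_along(x$terms), 6)
  cat("final estimates:",
      paste0(x$terms[show], " = ", format(fin[show], digits = 3),
             collapse = ", "),
      if (length(x$terms) > 6) "...", "\n")
  invisible(x)
}

#' Recover unobserved oscillator variables from one measured variable
#'
#' For a single (uncoupled) oscillator, runs the UKF on the three-variable
#' model observing only one noisy variable (by default y) and returns the
#' filtered estimates of all three variables with their one-standard-
#' deviation bands. Works equally when x or z is the observed variable.
#'
#' @param measurements Tibble with `time` and one measurement column (from
#'   [measure_trajectory()] with `observe` set accordingly), or a one-column
#'   matrix.
#' @param params,noise,sampling,config,seed As in [estimate_coupling()].
#' @param observe Which variable the measurements are of; defaults to the
#'   series' `observe` attribute, else `"y"`.
#' @param init_state_var Initial diagonal variance of the filter state.
#' @return An object of class `state_fit`: tibble-backed estimates with
#'   columns `time`, `x`, `y`, `z`, `x_sd`, `y_sd`, `z_sd`.
#' @export
recover_hidden_states <- function(measurements, params = oscillator_params(),
                                  noise = NULL, sampling = NULL,
                                  config = ukf_config(), observe = NULL,
                                  init_state_var = 1, n_cov_samples = 100000,
                                  seed = NULL) {
  mm <- meas_matrix(measurements)
  if (ncol(mm$values) != 1)
    abort("recover_hidden_states expects a single-oscillator series")
  if (is.null(observe)) observe <- attr(measurements, "observe")
  if (is.null(observe)) observe <- "y"
  dt <- resolve_dt(measurements, sampling)
  if (is.null(noise)) noise <- attr(measurements, "noise")
  if (is.null(noise) && (!is.matrix(config$Q_omega) || !is.matrix(config$Q_nu)))
    abort("supply a noise_spec (or matrix covariances in the config)")
  seeds <- split_seed(seed, c("q_omega", "q_nu"))
  Qw <- if (is.matrix(config$Q_omega)) config$Q_omega else
    estimate_noise_covariance(noise$sigma_omega, 3, n_cov_samples,
                              seeds$q_omega)
  Qnu <- if (is.matrix(config$Q_nu)) config$Q_nu else
    estimate_noise_covariance(noise$sigma_nu, 1, n_cov_samples, seeds$q_nu)
  obs0 <- obs_indices0(observe, 1)
  m0 <- numeric(3)
  m0[obs0 + 1] <- mm$values[1, 1]
  res <- .cpp_ukf_model(mm$values, obs0, dt, unclass(params),
                        matrix(0L, 1, 1), matrix(0, 1, 1), 0L,
                        Qw, Qnu, m0, diag(init_state_var, 3),
                        config$alpha_sp, config$beta_sp, config$kappa_sp)
  n <- nrow(mm$values)
  time <- if (!is.null(mm$time)) mm$time else (seq_len(n) - 1) * dt
  out <- tibble::tibble(
    time = time,
    x = res$mean[, 1], y = res$mean[, 2], z = res$mean[, 3],
    x_sd = res$sd[, 1], y_sd = res$sd[, 2], z_sd = res$sd[, 3]
  )
  structure(list(states = out, observe = observe,
                 jitter_events = res$jitter_events,
                 skipped_updates = res$skipped_updates),
            class = "state_fit")
}

#' @export
print.state_fit <- function(x, ...) {
  cat("<state_fit> filtered x/y/z over", nrow(x$states),
      "steps (observed:", x$observe, ")\n")
  invisible(x)
}
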