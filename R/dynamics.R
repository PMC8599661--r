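# Network simulator: piecewise-linear Rossler-like oscillators, diffusively
# coupled through their y variables, integrated with classical RK4 plus
# per-step additive Gaussian process noise; y-only noisy measurements.

#' Piecewise-linear switching nonlinearity
#'
#' The circuit nonlinearity driving the z variable: zero below the threshold
#' and linear with slope `mu` above it, `g(x) = mu * (x - v_th)` for
#' `x > v_th`. Continuous at `x = v_th` (the boundary belongs to the zero
#' branch).
#'
#' @param x Input value(s) (vectorized).
#' @param v_th Switching threshold (V).
#' @param mu Slope above threshold (>= 0).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' g_nonlinearity(c(2, 3.0088, 4.0088), v_th = 3.0088, mu = 15)
#' @export
g_nonlinearity <- function(x, v_th, mu) {
  stopifnot(all(is.finite(x)), is.finite(v_th), is.finite(mu))
  ifelse(x > v_th, mu * (x - v_th), 0)
}

state_labels <- function(n_nodes) {
  as.vector(vapply(seq_len(n_nodes),
                   function(i) paste0(c("x", "y", "z"), i), character(3)))
}

check_state <- function(state, net) {
  if (length(state) != 3 * net$n_nodes)
    abort(sprintf("state has length %d but the network needs 3N = %d",
                  length(state), 3 * net$n_nodes))
  invisible(TRUE)
}

#' Deterministic drift of the network state
#'
#' Time derivative of the full state `(x1, y1, z1, ..., xN, yN, zN)` under the
#' coupled oscillator equations: for node i,
#' \deqn{\dot x_i = -\alpha_1 (x_i + \beta y_i + \Gamma z_i)}
#' \deqn{\dot y_i = -\alpha_2 (-\gamma x_i + (1-\delta) y_i -
#'       K \phi \sum_j A_{ij} (y_j - y_i))}
#' \deqn{\dot z_i = -\alpha_3 (-\eta\, g(x_i) + z_i)}
#' Node i's coupling term involves only the y variables of its neighbours;
#' the origin is a fixed point for every network and coupling strength.
#'
#' @param state Numeric 3N-vector.
#' @param params [oscillator_params()].
#' @param net [network_model()].
#' @return Numeric 3N-vector of time derivatives.
#' @export
drift <- function(state, params = oscillator_params(), net) {
  check_state(state, net)
  as.vector(.cpp_drift(state, unclass(params), coupling_matrix(net)))
}

#' One fourth-order Runge-Kutta step
#'
#' Advances a state by `dt` with the classical RK4 scheme. By default the
#' drift is the coupled-oscillator field of [drift()]; any other
#' autonomous field can be supplied through `drift_fn` (used e.g. for
#' convergence checks against systems with a closed-form solution).
#'
#' @param state Numeric state vector.
#' @param dt Time step (> 0).
#' @param params,net Model and network (ignored when `drift_fn` is given).
#' @param drift_fn Optional function `f(state) -> dstate/dt`.
#' @return The advanced state vector; an error is raised if it is not finite.
#' @export
rk4_step <- function(state, dt, params = oscillator_params(), net = NULL,
                     drift_fn = NULL) {
  if (dt <= 0) abort("dt must be positive")
  if (is.null(drift_fn)) {
    check_state(state, net)
    out <- as.vector(.cpp_rk4_step(state, dt, unclass(params),
                                   coupling_matrix(net)))
  } else {
    k1 <- drift_fn(state)
    k2 <- drift_fn(state + dt / 2 * k1)
    k3 <- drift_fn(state + dt / 2 * k2)
    k4 <- drift_fn(state + dt * k3)
    out <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  if (!all(is.finite(out)))
    abort("RK4 step produced a non-finite state (numerical blow-up)")
  out
}

#' Simulate a stochastic network trajectory
#'
#' Iterates the discrete-time map `u[k+1] = rk4(u[k]) + omega[k]` where
#' `omega[k]` is i.i.d. zero-mean Gaussian with standard deviation
#' `noise$sigma_omega` in every component, added once per completed RK4 step.
#' The default initial condition is drawn uniformly from `[-0.1, 0.1]^(3N)`;
#' an initial transient of `discard` steps can be dropped so the returned
#' series starts on the attractor.
#'
#' @param net [network_model()].
#' @param params [oscillator_params()].
#' @param sampling [sampling_grid()]; `n_steps` rows are returned.
#' @param noise [noise_spec()]; only `sigma_omega` is used here.
#' @param init Optional numeric 3N initial state.
#' @param discard Number of leading steps to simulate and drop (default 0).
#' @param seed Master seed; deterministically split into independent
#'   sub-streams for the initial condition and the process noise.
#' @return A tibble with columns `time`, `x1`, `y1`, `z1`, ...; attributes
#'   `net`, `params`, `sampling`, `noise`, `seed` record the run.
#' @examples
#' net <- network_model(n_nodes = 1)
#' tr <- simulate_oscillators(net, sampling = sampling_grid(n_steps = 500),
#'                            seed = 1)
#' @export
simulate_oscillators <- function(net, params = oscillator_params(),
                                 sampling = sampling_grid(),
                                 noise = noise_spec(), init = NULL,
                                 discard = 0, seed = NULL) {
  d <- 3 * net$n_nodes
  seeds <- split_seed(seed, c("init", "process", "measurement"))
  if (is.null(init)) {
    init <- with_seed(seeds$init, runif(d, -0.1, 0.1))
  } else {
    check_state(init, net)
  }
  n_total <- sampling$n_steps + discard
  omega <- if (noise$sigma_omega > 0) {
    with_seed(seeds$process,
              matrix(rnorm((n_total - 1) * d, 0, noise$sigma_omega),
                     n_total - 1, d))
  } else {
    matrix(0, 0, d)
  }
  states <- .cpp_simulate(init, n_total, sampling$dt, unclass(params),
                          coupling_matrix(net), omega)
  if (discard > 0) states <- states[-seq_len(discard), , drop = FALSE]
  colnames(states) <- state_labels(net$n_nodes)
  out <- tibble::as_tibble(as.data.frame(states))
  out <- tibble::add_column(out,
    time = (seq_len(sampling$n_steps) - 1) * sampling$dt, .before = 1)
  attr(out, "net") <- net
  attr(out, "params") <- params
  attr(out, "sampling") <- sampling
  attr(out, "noise") <- noise
  attr(out, "seed") <- seed
  attr(out, "measurement_seed") <- seeds$measurement
  out
}

#' Noisy single-variable measurements of a trajectory
#'
#' Applies the measurement map selecting one variable per node (by default
#' the y columns, the variable through which the oscillators couple) and adds
#' i.i.d. zero-mean Gaussian noise with standard deviation `noise$sigma_nu`.
#'
#' @param trajectory A trajectory tibble from [simulate_oscillators()] (or
#'   any data frame with `time` and `x/y/z`-numbered columns).
#' @param noise [noise_spec()]; only `sigma_nu` is used. Defaults to the
#'   trajectory's own noise attribute.
#' @param observe Which variable is recorded: `"y"` (default), `"x"` or `"z"`.
#' @param seed Seed for the measurement-noise stream. Defaults to the
#'   measurement sub-stream of the trajectory's master seed.
#' @return A tibble with columns `time` and `y1 ... yN` (or `x*`/`z*`).
#' @export
measure_trajectory <- function(trajectory, noise = NULL,
                               observe = c("y", "x", "z"), seed = NULL) {
  observe <- match.arg(observe)
  if (is.null(noise)) noise <- attr(trajectory, "noise")
  if (is.null(noise)) abort("supply a noise_spec (trajectory carries none)")
  if (is.null(seed)) seed <- attr(trajectory, "measurement_seed")
  cols <- grep(paste0("^", observe, "[0-9]+$"), names(trajectory), value = TRUE)
  if (length(cols) == 0) abort(paste0("no ", observe, "* columns found"))
  vals <- as.matrix(trajectory[cols])
  if (noise$sigma_nu > 0) {
    vals <- vals + with_seed(seed,
      matrix(rnorm(length(vals), 0, noise$sigma_nu), nrow(vals), ncol(vals)))
  }
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- tibble::add_column(out, time = trajectory$time, .before = 1)
  attr(out, "observe") <- observe
  attr(out, "noise") <- noise
  attr(out, "sampling") <- attr(trajectory, "sampling")
  out
}
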