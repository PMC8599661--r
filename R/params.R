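# Model constants, sampling/noise settings, and network containers.

.presets <- list(
  n1_2 = list(
    params = list(alpha1 = 500, alpha2 = 200, alpha3 = 10000, beta = 10,
                  Gamma = 20, gamma = 50, delta = 8.3333, phi = 1,
                  eta = 1, mu = 15, v_th = 3.0088),
    f_s = 37000, n_steps = 100000,
    sigma_omega = 0.02, sigma_nu = 0.5
  ),
  n28 = list(
    params = list(alpha1 = 500, alpha2 = 200, alpha3 = 10000, beta = 10,
                  Gamma = 20, gamma = 50, delta = 8.6207, phi = 0.0210,
                  eta = 1, mu = 15, v_th = 2.1265),
    f_s = 30000, n_steps = 15000,
    sigma_omega = 0.001, sigma_nu = 0.001
  )
)

#' Oscillator model constants
#'
#' Named constants of the piecewise-linear Rossler-like circuit oscillator:
#' rate constants `alpha1`, `alpha2`, `alpha3` (1/s), dimensionless
#' coefficients `beta`, `Gamma`, `gamma`, `delta`, `phi`, `eta`, `mu`, and the
#' switching threshold `v_th` (V) of the piecewise nonlinearity. Two presets
#' ship with the package: `"n1_2"` (the single-node / two-node regime:
#' `delta = 8.3333`, `phi = 1`, `v_th = 3.0088`) and `"n28"` (the 28-node
#' regime: `delta = 8.6207`, `phi = 0.0210`, `v_th = 2.1265`). Any field can
#' be overridden through `...`.
#'
#' @param preset Character, `"n1_2"` (default) or `"n28"`.
#' @param ... Named overrides for individual constants.
#' @return An object of class `oscillator_params` (a named list).
#' @examples
#' oscillator_params()
#' oscillator_params("n28", mu = 14)
#' @export
oscillator_params <- function(preset = c("n1_2", "n28"), ...) {
  preset <- match.arg(preset)
  p <- .presets[[preset]]$params
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0)
    abort(paste0("unknown oscillator parameter(s): ",
                 paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  vals <- unlist(p)
  if (!all(is.finite(vals))) abort("all oscillator parameters must be finite")
  if (any(vals[c("alpha1", "alpha2", "alpha3")] <= 0))
    abort("alpha1, alpha2, alpha3 must be positive")
  if (p$mu < 0) abort("mu must be non-negative")
  structure(p, class = "oscillator_params", preset = preset)
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat("<oscillator_params> preset:", attr(x, "preset"), "\n")
  print(unlist(x))
  invisible(x)
}

#' Noise specification
#'
#' Standard deviations of the additive zero-mean Gaussian noise terms:
#' `sigma_omega` is the process (dynamical) noise added to every state
#' component once per integration step, `sigma_nu` the measurement noise
#' added to each observed component.
#'
#' @param sigma_omega,sigma_nu Non-negative standard deviations.
#' @param preset Optional preset name (`"n1_2"`: 0.02/0.5; `"n28"`:
#'   0.001/0.001) supplying defaults.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_omega = NULL, sigma_nu = NULL,
                       preset = c("n1_2", "n28")) {
  preset <- match.arg(preset)
  if (is.null(sigma_omega)) sigma_omega <- .presets[[preset]]$sigma_omega
  if (is.null(sigma_nu)) sigma_nu <- .presets[[preset]]$sigma_nu
  if (sigma_omega < 0 || sigma_nu < 0)
    abort("noise standard deviations must be non-negative")
  structure(list(sigma_omega = sigma_omega, sigma_nu = sigma_nu),
            class = "noise_spec")
}

#' Uniform sampling grid
#'
#' The time step is always derived from the sampling rate, `dt = 1/f_s`,
#' never set independently.
#'
#' @param f_s Sampling rate (samples/s).
#' @param n_steps Number of discrete time steps (>= 1).
#' @return An object of class `sampling_grid` with fields `f_s`, `dt`,
#'   `n_steps`.
#' @export
sampling_grid <- function(f_s = 37000, n_steps = 100000) {
  if (f_s <= 0) abort("f_s must be positive")
  n_steps <- as.integer(n_steps)
  if (n_steps < 1) abort("n_steps must be >= 1")
  structure(list(f_s = f_s, dt = 1 / f_s, n_steps = n_steps),
            class = "sampling_grid")
}

#' Coupled-oscillator network
#'
#' @param A Binary adjacency matrix (square, zero diagonal; symmetric unless
#'   `symmetric = FALSE`). For a single uncoupled oscillator use
#'   `network_model(n_nodes = 1)`.
#' @param K Coupling strength: a scalar applied to every edge of `A`, or an
#'   N x N matrix of per-ordered-pair couplings `K[i, j]` (in which case `A`
#'   may be omitted and is taken as `K != 0`).
#' @param n_nodes Node count, required when `A` is omitted.
#' @param symmetric Enforce `A[i, j] == A[j, i]` (default `TRUE`).
#' @return An object of class `network_model` with fields `n_nodes`, `A`, `K`.
#' @seealso [random_network()], [coupling_matrix()]
#' @export
network_model <- function(A = NULL, K = 1, n_nodes = NULL, symmetric = TRUE) {
  if (is.null(A)) {
    if (is.matrix(K)) {
      A <- (K != 0) * 1
    } else {
      if (is.null(n_nodes)) abort("supply either A or n_nodes")
      A <- matrix(0, n_nodes, n_nodes)
    }
  }
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) abort("A must be square")
  if (!all(A %in% c(0, 1))) abort("A must be binary (0/1)")
  if (any(diag(A) != 0)) abort("A must have a zero diagonal (no self-loops)")
  if (symmetric && !isTRUE(all.equal(A, t(A))))
    abort("A must be symmetric (set symmetric = FALSE for directed coupling)")
  if (is.matrix(K)) {
    if (!all(dim(K) == dim(A))) abort("K matrix must match A in shape")
    if (any(diag(K) != 0)) abort("K matrix must have a zero diagonal")
  } else {
    if (length(K) != 1 || !is.finite(K)) abort("K must be a finite scalar")
  }
  structure(list(n_nodes = nrow(A), A = A, K = K),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  ne <- sum(x$A[upper.tri(x$A)])
  cat("<network_model>", x$n_nodes, "nodes,", ne, "edges, K =",
      if (is.matrix(x$K)) "per-pair matrix" else x$K, "\n")
  invisible(x)
}

#' Effective coupling-weight matrix
#'
#' Returns the N x N matrix `W` with `W[i, j]` the effective coupling weight
#' multiplying `(y_j - y_i)` in node i's y-equation (before the global factor
#' `phi`): `K * A` for a scalar coupling strength, or the per-pair `K` matrix.
#'
#' @param net A [network_model()].
#' @return A numeric N x N matrix.
#' @export
coupling_matrix <- function(net) {
  stopifnot(inherits(net, "network_model"))
  if (is.matrix(net$K)) net$K else net$K * net$A
}

#' Seeded random network
#'
#' Uniformly samples an undirected edge set, giving a binary symmetric
#' adjacency matrix with zero diagonal.
#'
#' @param n_nodes Node count.
#' @param n_edges Number of undirected edges; at most `n_nodes*(n_nodes-1)/2`.
#' @param edge_density Alternative to `n_edges`: fraction of possible edges.
#' @param K Coupling strength stored on the returned network.
#' @param seed Integer seed for reproducibility.
#' @return A [network_model()].
#' @examples
#' random_network(28, edge_density = 0.2, seed = 1)
#' @export
random_network <- function(n_nodes, n_edges = NULL, edge_density = NULL,
                           K = 1, seed = NULL) {
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (is.null(n_edges)) {
    if (is.null(edge_density)) abort("supply n_edges or edge_density")
    n_edges <- round(edge_density * max_edges)
  }
  if (n_edges > max_edges)
    abort(sprintf("requested %d edges but only %d are possible for %d nodes",
                  n_edges, max_edges, n_nodes))
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  sel <- with_seed(seed, sample.int(max_edges, n_edges))
  A <- matrix(0, n_nodes, n_nodes)
  for (r in sel) {
    A[pairs[r, 1], pairs[r, 2]] <- 1
    A[pairs[r, 2], pairs[r, 1]] <- 1
  }
  network_model(A, K = K)
}

# Preset accessor used by config handling and experiments.
preset_defaults <- function(preset = c("n1_2", "n28")) {
  preset <- match.arg(preset)
  .presets[[preset]]
}
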