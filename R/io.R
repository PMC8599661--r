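# File formats and run configuration. All user-facing files are plain text:
# CSV time series with a leading time column (seconds) and a header row,
# adjacency matrices as whitespace-delimited dense matrices or two-column
# 1-based edge lists, and YAML run configs mirroring the parameter names.

#' Write / read a trajectory or measurement series as CSV
#'
#' First column `time` (seconds), remaining columns the named state or
#' measurement components (`x1,y1,z1,...` or `y1,...,yN`).
#'
#' @param x Tibble from [simulate_oscillators()] or [measure_trajectory()].
#' @param path Output file.
#' @return `write_series()` returns `path` invisibly; `read_series()` a
#'   tibble.
#' @export
write_series <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  if (!"time" %in% names(df)) abort("series file must have a 'time' column")
  df
}

#' Write / read an adjacency matrix
#'
#' Dense format: whitespace-delimited numeric matrix, one row per line.
#' Edge-list format: two columns of 1-based node indices, one undirected
#' edge per line (node count recovered from the indices or `n_nodes`).
#'
#' @param A Binary adjacency matrix.
#' @param path File path.
#' @param format `"matrix"` (default) or `"edgelist"`; `read_adjacency()`
#'   auto-detects by column count unless told otherwise.
#' @param n_nodes Node count for edge lists whose highest index is not the
#'   last node.
#' @return `write_adjacency()` returns `path` invisibly; `read_adjacency()`
#'   the matrix.
#' @export
write_adjacency <- function(A, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  if (format == "matrix") {
    utils::write.table(A, path, row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
    utils::write.table(idx[order(idx[, 1], idx[, 2]), , drop = FALSE], path,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path, format = c("auto", "matrix", "edgelist"),
                           n_nodes = NULL) {
  format <- match.arg(format)
  m <- as.matrix(read.table(path))
  if (format == "auto")
    format <- if (ncol(m) == 2 && nrow(m) != 2) "edgelist" else "matrix"
  if (format == "matrix") {
    dimnames(m) <- NULL
    return(m)
  }
  if (is.null(n_nodes)) n_nodes <- max(m)
  A <- matrix(0, n_nodes, n_nodes)
  for (r in seq_len(nrow(m))) {
    A[m[r, 1], m[r, 2]] <- 1
    A[m[r, 2], m[r, 1]] <- 1
  }
  A
}

#' Resolved run configuration
#'
#' Collects everything a simulate / infer / reconstruct run needs: the
#' parameter preset with optional overrides, network settings, run length,
#' filter settings, and the master seed. The resolved configuration is fully
#' concrete (every field has a value) and is persisted verbatim next to all
#' outputs, together with the package version.
#'
#' @param preset `"n1_2"` or `"n28"`; supplies defaults for the model
#'   constants, `f_s`, `n_steps` and the noise levels.
#' @param n_nodes Node count of the simulated network.
#' @param mode Inference mode: `"single_k"`, `"directional_pair"`,
#'   `"all_pairs"`, or `"hidden_states"` (single-node state recovery).
#' @param K True coupling strength used in simulation.
#' @param n_edges,edge_density Random-network edge budget (ignored when
#'   `adjacency` is supplied); defaults to `edge_density = 0.35`.
#' @param adjacency Optional explicit adjacency matrix (or path to one).
#' @param n_steps,f_s,sigma_omega,sigma_nu Overrides of the preset values.
#' @param discard Simulated transient steps dropped before recording
#'   (default 20000, so the series starts on the attractor).
#' @param init_guess,threshold,burn_fraction Filter / reconstruction
#'   settings.
#' @param alpha_sp,beta_sp,kappa_sp Sigma-point hyperparameters.
#' @param seed Master seed for the run.
#' @param params Named list of oscillator-constant overrides.
#' @return An object of class `run_config` (a fully resolved named list).
#' @export
run_config <- function(preset = c("n1_2", "n28"), n_nodes = 2,
                       mode = c("single_k", "directional_pair", "all_pairs",
                                "hidden_states"),
                       K = 0.5, n_edges = NULL, edge_density = NULL,
                       adjacency = NULL, n_steps = NULL, f_s = NULL,
                       sigma_omega = NULL, sigma_nu = NULL, discard = 20000,
                       init_guess = 0.5, threshold = 0.5, burn_fraction = 0.1,
                       alpha_sp = 1, beta_sp = 2, kappa_sp = 0, seed = 1,
                       params = list()) {
  preset <- match.arg(preset)
  mode <- match.arg(mode)
  def <- preset_defaults(preset)
  if (is.character(adjacency)) adjacency <- read_adjacency(adjacency)
  if (!is.null(adjacency)) n_nodes <- nrow(adjacency)
  if (is.null(n_edges) && is.null(edge_density) && is.null(adjacency))
    edge_density <- 0.35
  cfg <- list(
    preset = preset, n_nodes = as.integer(n_nodes), mode = mode, K = K,
    n_edges = n_edges, edge_density = edge_density, adjacency = adjacency,
    n_steps = as.integer(if (is.null(n_steps)) def$n_steps else n_steps),
    f_s = if (is.null(f_s)) def$f_s else f_s,
    sigma_omega = if (is.null(sigma_omega)) def$sigma_omega else sigma_omega,
    sigma_nu = if (is.null(sigma_nu)) def$sigma_nu else sigma_nu,
    discard = as.integer(discard), init_guess = init_guess,
    threshold = threshold, burn_fraction = burn_fraction,
    alpha_sp = alpha_sp, beta_sp = beta_sp, kappa_sp = kappa_sp,
    seed = as.integer(seed), params = params
  )
  must <- c("n_steps", "f_s", "sigma_omega", "sigma_nu", "K", "seed")
  bad <- must[!vapply(cfg[must], function(v)
    length(v) == 1 && is.finite(as.numeric(v)), logical(1))]
  if (length(bad) > 0)
    abort(paste0("config fields not resolved: ", paste(bad, collapse = ", ")))
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  do.call(oscillator_params, c(list(preset = cfg$preset), cfg$params))
}

config_network <- function(cfg, seed) {
  if (!is.null(cfg$adjacency))
    return(network_model(cfg$adjacency, K = cfg$K))
  if (cfg$n_nodes == 1) return(network_model(n_nodes = 1, K = cfg$K))
  random_network(cfg$n_nodes, n_edges = cfg$n_edges,
                 edge_density = cfg$edge_density, K = cfg$K, seed = seed)
}

config_ukf <- function(cfg) {
  ukf_config(alpha_sp = cfg$alpha_sp, beta_sp = cfg$beta_sp,
             kappa_sp = cfg$kappa_sp)
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  out <- unclass(cfg)
  if (!is.null(out$adjacency)) out$adjacency <- apply(out$adjacency, 1, c,
                                                      simplify = FALSE)
  out$package_version <- as.character(packageVersion("ukfnet"))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$package_version <- NULL
  if (!is.null(raw$adjacency)) {
    raw$adjacency <- if (is.list(raw$adjacency))
      do.call(rbind, raw$adjacency)
    else
      matrix(raw$adjacency, nrow = 1)
  }
  do.call(run_config, raw)
}

#' Pipeline entry points (simulate / infer / reconstruct)
#'
#' Thin, file-oriented wrappers tying the package together; these back the
#' `inst/cli/ukfnet` command-line script. Each writes its outputs plus the
#' resolved configuration into `out_dir` and returns the written paths
#' invisibly. Node indices in all files are 1-based.
#'
#' `cli_simulate()` writes `trajectory.csv`, `measurements.csv`,
#' `adjacency.txt` and `config.yaml`. `cli_infer()` reads a measurement CSV
#' and writes `estimate_trace.csv` (step, time, one value and one sigma
#' column per parameter) and `metadata.json`. `cli_reconstruct()` runs the
#' all-pairs pipeline and writes `adjacency_estimate.txt`,
#' `edge_summary.csv`, `distance_trace.csv` (when a truth matrix is given)
#' and `metadata.json`.
#'
#' @param config A [run_config()] (or path to a YAML one).
#' @param out_dir Output directory (created if missing).
#' @param measurements_file CSV of measurements (from `cli_simulate()`).
#' @param truth_file Optional path to the true adjacency/coupling matrix.
#' @return Named character vector of written paths, invisibly.
#' @export
cli_simulate <- function(config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(cfg$seed, c("network", "simulate"))
  net <- config_network(cfg, seeds$network)
  tr <- simulate_oscillators(
    net, params = config_params(cfg),
    sampling = sampling_grid(cfg$f_s, cfg$n_steps),
    noise = noise_spec(cfg$sigma_omega, cfg$sigma_nu),
    discard = cfg$discard, seed = seeds$simulate)
  ms <- measure_trajectory(tr)
  paths <- c(trajectory = file.path(out_dir, "trajectory.csv"),
             measurements = file.path(out_dir, "measurements.csv"),
             adjacency = file.path(out_dir, "adjacency.txt"),
             config = file.path(out_dir, "config.yaml"))
  write_series(tr, paths["trajectory"])
  write_series(ms, paths["measurements"])
  write_adjacency(net$A, paths["adjacency"])
  cfg$adjacency <- net$A
  write_run_config(cfg, paths["config"])
  invisible(paths)
}

#' @rdname cli_simulate
#' @export
cli_infer <- function(measurements_file, config, out_dir) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ms <- read_series(measurements_file)
  n_obs <- ncol(ms) - 1
  noise <- noise_spec(cfg$sigma_omega, cfg$sigma_nu)
  seeds <- split_seed(cfg$seed, c("network", "infer"))
  paths <- c(trace = file.path(out_dir, "estimate_trace.csv"),
             metadata = file.path(out_dir, "metadata.json"),
             config = file.path(out_dir, "config.yaml"))
  if (cfg$mode == "hidden_states") {
    if (n_obs != 1) abort("hidden_states mode expects a single-column series")
    fit <- recover_hidden_states(ms, params = config_params(cfg),
                                 noise = noise, config = config_ukf(cfg),
                                 seed = seeds$infer)
    write.csv(as.data.frame(fit$states), paths["trace"], row.names = FALSE)
    meta <- list(mode = cfg$mode, jitter_events = fit$jitter_events,
                 skipped_updates = fit$skipped_updates)
  } else {
    if (cfg$mode == "single_k" && is.null(cfg$adjacency))
      abort("single_k mode needs the known adjacency in the config")
    net <- if (!is.null(cfg$adjacency))
      network_model(cfg$adjacency, K = cfg$K) else NULL
    fit <- estimate_coupling(ms, mode = cfg$mode, net = net,
                             params = config_params(cfg), noise = noise,
                             config = config_ukf(cfg),
                             init_guess = cfg$init_guess, seed = seeds$infer)
    tr <- data.frame(step = seq_len(fit$n_steps), time = fit$time)
    for (j in seq_along(fit$terms)) {
      tr[[fit$terms[j]]] <- fit$estimate[, j]
      tr[[paste0(fit$terms[j], "_sd")]] <- fit$sd[, j]
    }
    write.csv(tr, paths["trace"], row.names = FALSE)
    meta <- list(mode = cfg$mode, terms = fit$terms,
                 final_estimate = as.numeric(fit$estimate[fit$n_steps, ]),
                 jitter_events = fit$jitter_events,
                 skipped_updates = fit$skipped_updates)
  }
  meta$seed <- cfg$seed
  meta$package_version <- as.character(packageVersion("ukfnet"))
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE, digits = NA)
  write_run_config(cfg, paths["config"])
  invisible(paths)
}

#' @rdname cli_simulate
#' @export
cli_reconstruct <- function(measurements_file, config, out_dir,
                            truth_file = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ms <- read_series(measurements_file)
  truth <- if (!is.null(truth_file)) {
    tm <- read_adjacency(truth_file)
    if (any(diag(tm) != 0)) abort("malformed truth matrix: non-zero diagonal")
    tm * cfg$K
  }
  seeds <- split_seed(cfg$seed, c("network", "infer"))
  rec <- reconstruct_network(ms, truth = truth, threshold = cfg$threshold,
                             burn_fraction = cfg$burn_fraction,
                             params = config_params(cfg),
                             noise = noise_spec(cfg$sigma_omega, cfg$sigma_nu),
                             config = config_ukf(cfg), seed = seeds$infer,
                             init_guess = cfg$init_guess)
  paths <- c(adjacency = file.path(out_dir, "adjacency_estimate.txt"),
             edges = file.path(out_dir, "edge_summary.csv"),
             metadata = file.path(out_dir, "metadata.json"),
             config = file.path(out_dir, "config.yaml"))
  write_adjacency(rec$adjacency, paths["adjacency"])
  es <- rec$edge_summary
  es$outliers <- NULL
  write.csv(as.data.frame(es), paths["edges"], row.names = FALSE)
  if (!is.null(rec$distance_trace)) {
    paths <- c(paths, distance = file.path(out_dir, "distance_trace.csv"))
    write.csv(as.data.frame(rec$distance_trace), paths["distance"],
              row.names = FALSE)
  }
  meta <- list(mode = "all_pairs", threshold = rec$threshold,
               burn_fraction = rec$burn_fraction, final_d = rec$final_d,
               d_thresholded = rec$d_thresholded, accuracy = rec$accuracy,
               n_links = sum(rec$adjacency) / 2, seed = cfg$seed,
               jitter_events = rec$fit$jitter_events,
               package_version = as.character(packageVersion("ukfnet")))
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA, na = "null")
  write_run_config(cfg, paths["config"])
  invisible(paths)
}

#' Coupling-strength recovery sweep
#'
#' For each true coupling strength in `k_values`, simulates a fresh two-node
#' (or `n_nodes`-node) data set, estimates `K`, and reports the post-burn-in
#' median, the final estimate and its one-sigma band. Reproduces the
#' recovery-versus-truth comparison across the synchronization range.
#'
#' @param k_values True coupling strengths (default the 0 to 1 grid in steps
#'   of 0.2).
#' @param n_steps Filter run length per grid point.
#' @param n_nodes Node count (default 2, the minimal motif; nodes are fully
#'   connected).
#' @param preset Parameter preset.
#' @param discard Simulated transient dropped before recording.
#' @param burn_fraction Burn-in for the median summary.
#' @param seed Master seed; each grid point gets an independent sub-stream.
#' @param config [ukf_config()].
#' @return A tibble with one row per grid point: `K_true`, `median`,
#'   `final`, `final_sd`, `abs_error` (median vs truth).
#' @export
sweep_coupling <- function(k_values = seq(0, 1, by = 0.2), n_steps = 50000,
                           n_nodes = 2, preset = "n1_2", discard = 20000,
                           burn_fraction = 0.1, seed = 1,
                           config = ukf_config()) {
  def <- preset_defaults(preset)
  seeds <- split_seed(seed, paste0("k", seq_along(k_values)))
  purrr::map_dfr(seq_along(k_values), function(idx) {
    K <- k_values[idx]
    A <- matrix(1, n_nodes, n_nodes) - diag(n_nodes)
    net <- network_model(A, K = K)
    tr <- simulate_oscillators(
      net, params = oscillator_params(preset),
      sampling = sampling_grid(def$f_s, n_steps),
      noise = noise_spec(preset = preset), discard = discard,
      seed = seeds[[idx]])
    ms <- measure_trajectory(tr)
    fit <- estimate_coupling(ms, mode = "single_k", net = net,
                             params = oscillator_params(preset),
                             config = config, seed = seeds[[idx]])
    med <- summarize_trace(as.numeric(fit$estimate[, 1]), burn_fraction)$median
    tibble::tibble(K_true = K, median = med,
                   final = fit$estimate[n_steps, 1],
                   final_sd = fit$sd[n_steps, 1],
                   abs_error = abs(med - K))
  })
}
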