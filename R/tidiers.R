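# Broom-style accessors and ggplot2 visualisations for the fitted objects.

#' Tidy a coupling fit
#'
#' One row per time step and parameter: `step`, `time`, `term`, `estimate`
#' and the one-standard-deviation band `sd` (square root of the parameter's
#' diagonal entry in the estimated state covariance).
#'
#' @param x A `coupling_fit` from [estimate_coupling()].
#' @param ... Unused.
#' @return A tibble in long format.
#' @export
tidy.coupling_fit <- function(x, ...) {
  est <- tibble::as_tibble(as.data.frame(x$estimate))
  names(est) <- x$terms
  est$step <- seq_len(x$n_steps)
  est$time <- x$time
  long <- tidyr::pivot_longer(est, -c("step", "time"), names_to = "term",
                              values_to = "estimate")
  sdt <- tibble::as_tibble(as.data.frame(x$sd))
  names(sdt) <- x$terms
  sdt$step <- seq_len(x$n_steps)
  sdl <- tidyr::pivot_longer(sdt, -"step", names_to = "term",
                             values_to = "sd")
  dplyr::arrange(dplyr::left_join(long, sdl, by = c("step", "term")),
                 .data$term, .data$step)
}

#' Glance at a coupling fit
#'
#' @param x A `coupling_fit`.
#' @param ... Unused.
#' @return A one-row tibble: mode, node and parameter counts, run length,
#'   numerical-safeguard event counts.
#' @export
glance.coupling_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, n_nodes = x$n_nodes,
                 n_parameters = length(x$terms), n_steps = x$n_steps,
                 jitter_events = x$jitter_events,
                 skipped_updates = x$skipped_updates)
}

#' @rdname tidy.coupling_fit
#' @export
tidy.state_fit <- function(x, ...) {
  long <- tidyr::pivot_longer(x$states[c("time", "x", "y", "z")], -"time",
                              names_to = "variable", values_to = "estimate")
  sds <- tidyr::pivot_longer(
    x$states[c("time", "x_sd", "y_sd", "z_sd")], -"time",
    names_to = "variable", values_to = "sd")
  sds$variable <- sub("_sd$", "", sds$variable)
  dplyr::left_join(long, sds, by = c("time", "variable"))
}

#' @rdname tidy.coupling_fit
#' @export
tidy.network_reconstruction <- function(x, ...) {
  dplyr::select(x$edge_summary, -"outliers")
}

#' Glance at a network reconstruction
#'
#' @param x A `network_reconstruction`.
#' @param ... Unused.
#' @return A one-row tibble: inferred link count, threshold, final distance
#'   `D`, distance of the thresholded matrix, and pair-classification
#'   accuracy (the last three are `NA` without a truth matrix).
#' @export
glance.network_reconstruction <- function(x, ...) {
  tibble::tibble(n_nodes = x$fit$n_nodes, n_links = sum(x$adjacency) / 2,
                 threshold = x$threshold, final_d = x$final_d,
                 d_thresholded = x$d_thresholded, accuracy = x$accuracy)
}

#' Plot a coupling-estimate trace
#'
#' Estimate trajectories with their plus/minus one-standard-deviation bands,
#' one facet per parameter (faceting is dropped for single-parameter fits).
#'
#' @param object A `coupling_fit`.
#' @param truth Optional named or unnamed numeric vector of true values to
#'   draw as horizontal reference lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coupling_fit <- function(object, truth = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$estimate - .data$sd,
                                      ymax = .data$estimate + .data$sd),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "coupling estimate")
  if (!is.null(truth)) {
    tr <- tibble::tibble(
      term = if (!is.null(names(truth))) names(truth) else object$terms,
      value = as.numeric(truth))
    p <- p + ggplot2::geom_hline(data = tr,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dashed")
  }
  if (length(object$terms) > 1)
    p <- p + ggplot2::facet_wrap(~term)
  p
}

#' Plot recovered state variables
#'
#' @param object A `state_fit` from [recover_hidden_states()].
#' @param reference Optional trajectory tibble (noise-free truth) overlaid
#'   as points.
#' @param ... Unused.
#' @return A ggplot object faceted by variable.
#' @export
autoplot.state_fit <- function(object, reference = NULL, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "filtered state")
  if (!is.null(reference)) {
    ref <- tidyr::pivot_longer(
      dplyr::rename_with(reference[c("time", "x1", "y1", "z1")],
                         ~sub("1$", "", .x)),
      -"time", names_to = "variable", values_to = "estimate")
    p <- p + ggplot2::geom_point(data = ref, size = 0.2, alpha = 0.3,
                                 colour = "grey40")
  }
  p
}

#' Plot a network reconstruction
#'
#' `type = "traces"` shows every per-edge estimate trace coloured by its
#' thresholded classification; `type = "distance"` shows the distance D
#' between estimated and true coupling matrices over filter steps (requires
#' a truth matrix).
#'
#' @param object A `network_reconstruction`.
#' @param type `"traces"` or `"distance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.network_reconstruction <- function(object,
                                            type = c("traces", "distance"),
                                            ...) {
  type <- match.arg(type)
  if (type == "distance") {
    if (is.null(object$distance_trace))
      abort("no distance trace: reconstruction was run without a truth matrix")
    return(
      ggplot2::ggplot(object$distance_trace,
                      ggplot2::aes(x = .data$step, y = .data$D)) +
        ggplot2::geom_line(colour = "steelblue") +
        ggplot2::labs(x = "filter step", y = "distance D")
    )
  }
  df <- tidy(object$fit)
  cls <- tibble::tibble(term = object$edge_summary$term,
                        link = object$edge_summary$link)
  df <- dplyr::left_join(df, cls, by = "term")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   group = .data$term,
                                   colour = .data$link)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "edge coupling estimate",
                  colour = "link")
}
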