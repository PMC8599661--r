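# From per-edge estimate traces to a binary network: boxplot-style
# summaries of the post-burn-in traces, a 0.5 threshold, and the Euclidean
# matrix distance D between true and reconstructed coupling matrices.

#' Summarize an estimate trace after burn-in
#'
#' Drops the first `burn_fraction` of the trace and reports boxplot-style
#' statistics of the retained samples: median, extrema (the whiskers), the
#' quartiles, and the outliers beyond 1.5 IQR from the quartiles (the
#' standard boxplot rule).
#'
#' @param x A numeric trace, or a `coupling_fit` (one summary row per
#'   parameter).
#' @param burn_fraction Fraction of leading samples to discard (default 0.1,
#'   i.e. the last 90% of the trace is kept).
#' @param ... Passed between methods.
#' @return A tibble with columns `median`, `min`, `max`, `q1`, `q3`,
#'   `n_retained`, `n_outliers` and a list-column `outliers`; the
#'   `coupling_fit` method prepends a `term` column.
#' @export
summarize_trace <- function(x, burn_fraction = 0.1, ...) {
  UseMethod("summarize_trace")
}

#' @rdname summarize_trace
#' @export
summarize_trace.numeric <- function(x, burn_fraction = 0.1, ...) {
  n <- length(x)
  start <- floor(burn_fraction * n) + 1
  if (start > n) abort("empty retained window after burn-in")
  keep <- x[seq(start, n)]
  qs <- quantile(keep, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- qs[3] - qs[1]
  out <- keep[keep < qs[1] - 1.5 * iqr | keep > qs[3] + 1.5 * iqr]
  tibble::tibble(median = qs[2], min = min(keep), max = max(keep),
                 q1 = qs[1], q3 = qs[3], n_retained = length(keep),
                 n_outliers = length(out), outliers = list(out))
}

#' @rdname summarize_trace
#' @export
summarize_trace.coupling_fit <- function(x, burn_fraction = 0.1, ...) {
  res <- purrr::map_dfr(seq_along(x$terms), function(j) {
    summarize_trace(as.numeric(x$estimate[, j]), burn_fraction)
  })
  tibble::add_column(res, term = x$terms, .before = 1)
}

#' Threshold per-edge estimates into a binary adjacency matrix
#'
#' Edges whose estimate is strictly above the threshold become 1 (in both
#' orientations), all others 0; the diagonal is always 0. An estimate exactly
#' at the threshold is classified as no link.
#'
#' @param edge_estimates Per-pair estimates covering all `i < j` pairs: a
#'   numeric vector in row-wise upper-triangle order (or named `K<i>_<j>`),
#'   or a data frame with columns `i`, `j` and `estimate` (or `median`).
#' @param threshold Classification threshold (default 0.5).
#' @param n_nodes Node count; inferred from the number of pairs when omitted.
#' @return A binary symmetric `n_nodes` x `n_nodes` matrix.
#' @examples
#' threshold_adjacency(c(0.9, 0.2, -0.1), n_nodes = 3)
#' @export
threshold_adjacency <- function(edge_estimates, threshold = 0.5,
                                n_nodes = NULL) {
  if (is.data.frame(edge_estimates)) {
    df <- edge_estimates
    val_col <- intersect(c("estimate", "median"), names(df))[1]
    if (is.na(val_col) || !all(c("i", "j") %in% names(df)))
      abort("data-frame estimates need columns i, j and estimate/median")
    if (is.null(n_nodes)) n_nodes <- max(df$i, df$j)
    vals <- df[[val_col]]
    ii <- df$i
    jj <- df$j
  } else {
    vals <- as.numeric(edge_estimates)
    if (is.null(n_nodes)) {
      n_nodes <- (1 + sqrt(1 + 8 * length(vals))) / 2
      if (n_nodes != round(n_nodes))
        abort("length of edge_estimates is not N(N-1)/2 for any integer N")
      n_nodes <- as.integer(n_nodes)
    }
    pr <- pair_index(n_nodes)
    ii <- pr$i
    jj <- pr$j
  }
  if (length(vals) != n_nodes * (n_nodes - 1) / 2)
    abort("estimates must cover all i < j pairs exactly once")
  A <- matrix(0, n_nodes, n_nodes)
  link <- vals > threshold
  A[cbind(ii, jj)[link, , drop = FALSE]] <- 1
  A[cbind(jj, ii)[link, , drop = FALSE]] <- 1
  A
}

# Row-wise upper-triangle pair order (i < j), matching the all_pairs
# parameter labels K<i>_<j>.
pair_index <- function(n_nodes) {
  i <- rep(seq_len(n_nodes - 1), times = (n_nodes - 1):1)
  j <- unlist(lapply(seq_len(n_nodes - 1), function(a) seq(a + 1, n_nodes)))
  list(i = i, j = j)
}

#' Euclidean distance between coupling matrices
#'
#' Root-sum-of-squares discrepancy over all entries (i, j):
#' \deqn{D(K, K') = \sqrt{\sum_{i,j} (K_{ij} - K'_{ij})^2}.}
#' Symmetric pairs are counted twice, as the sum runs over the full matrix.
#'
#' @param K_true,K_est Numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
coupling_distance <- function(K_true, K_est) {
  if (!all(dim(K_true) == dim(K_est)))
    abort("matrices must have the same shape")
  sqrt(sum((K_true - K_est)^2))
}

#' Reconstruct a network from y-only measurements
#'
#' The full pipeline behind the package: all-pairs coupling estimation
#' ([estimate_coupling()]), post-burn-in summaries of every per-edge trace
#' ([summarize_trace()]), thresholding of the medians into a binary adjacency
#' matrix ([threshold_adjacency()]), and - when the true coupling matrix is
#' supplied - a per-step distance trace and the final distance
#' ([coupling_distance()]) plus the fraction of correctly classified pairs.
#'
#' @param measurements Tibble of y measurements (`time`, `y1 ... yN`),
#'   N >= 3.
#' @param truth Optional true coupling matrix `K * A` (or a
#'   [network_model()]) used for the distance trace and the accuracy.
#' @param threshold Classification threshold on the post-burn-in medians.
#' @param burn_fraction Burn-in fraction for the summaries (default 0.1).
#' @inheritParams estimate_coupling
#' @param ... Passed on to [estimate_coupling()].
#' @return An object of class `network_reconstruction` with fields `fit`
#'   (the `coupling_fit`), `edge_summary` (tibble with `i`, `j`, `term`,
#'   boxplot statistics and `link`), `adjacency` (binary matrix),
#'   `distance_trace` (tibble `step`, `time`, `D`; truth only), `final_d`,
#'   `d_thresholded`, `accuracy`, `threshold`, `burn_fraction`, `truth`.
#' @export
reconstruct_network <- function(measurements, truth = NULL, threshold = 0.5,
                                burn_fraction = 0.1,
                                params = oscillator_params("n28"),
                                noise = NULL, sampling = NULL,
                                config = ukf_config(), seed = NULL, ...) {
  mm <- meas_matrix(measurements)
  if (ncol(mm$values) < 3)
    abort("all-pairs reconstruction needs N >= 3 nodes")
  fit <- estimate_coupling(measurements, mode = "all_pairs", params = params,
                           noise = noise, sampling = sampling,
                           config = config, seed = seed, ...)
  smry <- summarize_trace(fit, burn_fraction)
  pr <- pair_index(fit$n_nodes)
  edge_summary <- tibble::add_column(smry, i = pr$i, j = pr$j, .before = 1)
  edge_summary$link <- edge_summary$median > threshold
  A_est <- threshold_adjacency(edge_summary$median, threshold, fit$n_nodes)
  distance_trace <- NULL
  final_d <- d_thresholded <- accuracy <- NA_real_
  if (!is.null(truth)) {
    if (inherits(truth, "network_model")) truth <- coupling_matrix(truth)
    truth <- as.matrix(truth)
    if (!all(dim(truth) == fit$n_nodes))
      abort("truth matrix shape does not match the measurement columns")
    tv <- truth[cbind(pr$i, pr$j)]
    # D_k over all (i,j): each i<j pair discrepancy appears twice
    dev2 <- sweep(fit$estimate, 2, tv)^2
    D <- sqrt(2 * rowSums(dev2))
    distance_trace <- tibble::tibble(step = seq_len(fit$n_steps),
                                     time = fit$time, D = D)
    final_d <- D[fit$n_steps]
    d_thresholded <- coupling_distance(truth, A_est)
    accuracy <- mean((edge_summary$median > threshold) == (tv > threshold))
  }
  structure(list(fit = fit, edge_summary = edge_summary, adjacency = A_est,
                 distance_trace = distance_trace, final_d = final_d,
                 d_thresholded = d_thresholded, accuracy = accuracy,
                 threshold = threshold, burn_fraction = burn_fraction,
                 truth = truth),
            class = "network_reconstruction")
}

#' @export
print.network_reconstruction <- function(x, ...) {
  cat("<network_reconstruction>", x$fit$n_nodes, "nodes,",
      sum(x$adjacency) / 2, "inferred links (threshold", x$threshold, ")\n")
  if (!is.na(x$final_d))
    cat("final D =", format(x$final_d, digits = 4),
        "| D(thresholded) =", format(x$d_thresholded, digits = 4),
        "| pair accuracy =", format(x$accuracy, digits = 4), "\n")
  invisible(x)
}
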