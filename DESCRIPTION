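Package: ukfnet
Title: Network Inference for Coupled Chaotic Oscillators via Unscented
    Kalman Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of diffusively coupled Rossler-like chaotic
    oscillators with process and measurement noise, and infers their coupling
    strengths and adjacency matrix from noisy observations of a single
    variable per node. Joint state-parameter estimation is performed with an
    unscented Kalman filter (UKF) on a state vector augmented with the unknown
    couplings, which evolve with trivial (constant) dynamics and zero process
    noise. Per-edge estimate traces are summarised, thresholded into a binary
    adjacency matrix, and scored against a known truth with a Euclidean
    matrix distance. Includes a self-contained UKF for arbitrary transition
    and measurement maps, a fast compiled path for the oscillator model,
    tidy accessors and ggplot2 visualisations for all result types, and a
    command-line interface for the simulate/infer/reconstruct pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
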