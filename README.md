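# ukfnet

Network inference for coupled chaotic oscillators via unscented Kalman
filtering.

`ukfnet` is for researchers who ask: *given noisy recordings of one variable
per node, which nodes of a nonlinear oscillator network are connected, and
how strongly?* When the node dynamics are known up to the coupling
constants, connectivity inference becomes parameter estimation, and the
package solves it by data assimilation: a Kalman filter jointly estimates
the hidden state of every oscillator and the unknown couplings.

## The model and the method

Each node of an N-node network is a piecewise-linear Rössler-like chaotic
oscillator (the electronic-circuit variant), diffusively coupled through its
y variable:

    ẋᵢ = −α₁ (xᵢ + β yᵢ + Γ zᵢ)
    ẏᵢ = −α₂ (−γ xᵢ + (1 − δ) yᵢ − K φ Σⱼ Aᵢⱼ (yⱼ − yᵢ))
    żᵢ = −α₃ (−η g(xᵢ) + zᵢ),   g(x) = μ (x − V_th) for x > V_th, else 0

with A a binary symmetric adjacency matrix and K the coupling strength.
Discretised by one fourth-order Runge–Kutta step per sample
(dt = 1/f_s) plus additive Gaussian process noise σ_ω, and observed as
w = (y₁, …, y_N) + ν with measurement noise σ_ν, this is a noisy Markov
process — exactly what an unscented Kalman filter (UKF) assimilates.

The unknown couplings are appended to the state with constant dynamics
(ṗ = 0) and **zero** process noise, so the extended process covariance is
`blockdiag(Q_ω, 0)`. Running the UKF over the measurement series then yields
per-step estimates of every coupling with uncertainty bands (the square root
of the corresponding covariance diagonal). Three modes: estimate a single K
with known topology; estimate the two directed couplings of a pair; or
estimate all N(N−1)/2 pairwise couplings K·Aᵢⱼ, threshold their post-burn-in
medians at 0.5, and read off the adjacency matrix. Reconstruction quality
against a known truth is scored by the Euclidean matrix distance
D = √Σᵢⱼ (Kᵢⱼ − Kᵢⱼᵉˢᵗ)².

The filter core (and the simulator) are compiled (Rcpp/RcppArmadillo); a
10⁵-step run on the 7-dimensional augmented two-node state takes about a
second. A generic pure-R UKF (`ukf_filter()`) accepting arbitrary transition
and measurement maps is also exported and is the reference surface for the
filter's unit tests.

## Worked example

Simulate a two-node motif at K = 0.1, record noisy y traces, and recover K
from them:

```r
library(ukfnet)

net <- network_model(matrix(c(0, 1, 1, 0), 2), K = 0.1)
trajectory <- simulate_oscillators(
  net, sampling = sampling_grid(f_s = 37000, n_steps = 20000),
  discard = 20000, seed = 7)
measurements <- measure_trajectory(trajectory)
measurements
#> # A tibble: 20,000 × 3
#>        time    y1     y2
#>       <dbl> <dbl>  <dbl>
#> 1 0         -3.82 -1.18
#> 2 0.0000270 -4.53 -0.812
#> 3 0.0000541 -4.89 -1.52
#> # ℹ 19,997 more rows

fit <- estimate_coupling(measurements, mode = "single_k", net = net, seed = 7)
summarize_trace(fit)
#> # A tibble: 1 × 9
#>   term  median    min   max    q1    q3 n_retained n_outliers outliers
#>   <chr>  <dbl>  <dbl> <dbl> <dbl> <dbl>      <int>      <int> <list>
#> 1 K      0.136 0.0915 0.202 0.121 0.146      18000       1110 <dbl [1,110]>
```

The post-burn-in median is 0.136 with a final one-sigma band of ±0.023 — the
true K = 0.1 sits inside the ±2σ band, and the band keeps shrinking with run
length (at 10⁵ steps it is about ±0.01). `tidy(fit)` gives the full
per-step trace, `autoplot(fit, truth = c(K = 0.1))` plots it with its
uncertainty ribbon.

Topology reconstruction from scratch — 8 nodes, all 28 pairwise couplings
estimated jointly, no topology assumed:

```r
net8 <- random_network(8, edge_density = 0.35, K = 1, seed = 1)
tr8 <- simulate_oscillators(net8, params = oscillator_params("n28"),
                            sampling = sampling_grid(30000, 15000),
                            noise = noise_spec(preset = "n28"),
                            discard = 20000, seed = 1)
rec <- reconstruct_network(measure_trajectory(tr8), truth = net8, seed = 1)
rec
#> <network_reconstruction> 8 nodes, 10 inferred links (threshold 0.5 )
#> final D = 0.2236 | D(thresholded) = 0 | pair accuracy = 1
```

All 10 true links are recovered and no spurious link appears:
`D(thresholded) = 0` means the thresholded matrix equals the truth exactly.
The same code path scales to the 28-node, 378-parameter experiment
(`scripts/full_n28.R`, long-running).

A command-line interface wrapping the same functions ships at
`inst/cli/ukfnet` (subcommands `simulate`, `infer`, `reconstruct`, `sweep`),
reading YAML run configs and writing plain-text bundles with the resolved
configuration alongside every output.

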