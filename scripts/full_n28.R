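#!/usr/bin/env Rscript
# Optional long-running experiment: all-pairs inference of the 378 coupling
# parameters of a 28-node random network at K = 1 (462-dimensional augmented
# state). This is deliberately NOT part of the test suite or the acceptance
# script: expect on the order of an hour on one CPU. The desk-scale
# equivalent (N = 8) is covered by the tests and scripts/acceptance.R.
#
# Usage: Rscript scripts/full_n28.R [--seed <int>] [--steps <int>] [--out dir]

suppressPackageStartupMessages(library(ukfnet))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, steps = 15000L, out = "results/n28")
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  if (!key %in% names(opt)) stop("unknown argument: ", args[i])
  opt[[key]] <- if (key == "out") args[i + 1] else as.integer(args[i + 1])
  i <- i + 2
}

set.seed(opt$seed)
seeds <- sample.int(2^31 - 2, 2)

net <- random_network(28, edge_density = 0.2, K = 1, seed = seeds[1])
message("simulating 28-node network (", sum(net$A) / 2, " edges) ...")
tr <- simulate_oscillators(net, params = oscillator_params("n28"),
                           sampling = sampling_grid(30000, opt$steps),
                           noise = noise_spec(preset = "n28"),
                           discard = 20000, seed = seeds[2])
ms <- measure_trajectory(tr)

message("running all-pairs UKF (462-dimensional state, 378 parameters) ...")
t0 <- Sys.time()
rec <- reconstruct_network(ms, truth = net, threshold = 0.5,
                           params = oscillator_params("n28"),
                           seed = seeds[2])
message("filter time: ", format(Sys.time() - t0))
print(glance(rec))

dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
write_adjacency(rec$adjacency, file.path(opt$out, "adjacency_estimate.txt"))
write_adjacency(net$A, file.path(opt$out, "adjacency_truth.txt"))
es <- rec$edge_summary
es$outliers <- NULL
write.csv(as.data.frame(es), file.path(opt$out, "edge_summary.csv"),
          row.names = FALSE)
write.csv(as.data.frame(rec$distance_trace),
          file.path(opt$out, "distance_trace.csv"), row.names = FALSE)
message("final D = ", rec$final_d, "; D(thresholded) = ", rec$d_thresholded,
        "; pair accuracy = ", rec$accuracy)
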