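#!/usr/bin/env Rscript
# Full-scale neural-network decoding run on Example 1: N = 1e5 trajectories
# per input, d = 100. This reproduces the deep-training regime in which the
# MLP decoder approaches ~0.65 bits; it takes hours of CPU time and is
# therefore not part of the default test run.
#
# usage: Rscript scripts/nn_fullscale.R [--seed S] [--n N]

suppressPackageStartupMessages(library(trajinfo))
args <- commandArgs(trailingOnly = TRUE)
opt <- list(seed = 1L, n = 1e5)
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--n") { opt$n <- as.numeric(args[i + 1L]); i <- i + 2L }
  else stop("unknown argument: ", args[i])
}

ex <- make_example(1)
message("simulating ", opt$n, " paths per input ...")
tset <- simulate_dataset(ex$network, ex$ensemble, ex$x0, ex$T,
                         as.integer(opt$n), seed = opt$seed)
dat <- resample_dataset(tset, 100L)
res <- estimate_info(dat, decoder_spec("mlp"), replicates = 5L,
                     seed = opt$seed + 1L)
message(sprintf("I_NN (Example 1, d = 100, N = %g): %.4f +- %.4f bits",
                opt$n, res$value, res$std))
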