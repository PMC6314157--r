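#!/usr/bin/env Rscript

# Thin command-line wrapper over pedimpute::run_pipeline().
#
# Usage: Rscript scripts/run_pipeline.R <config.yaml>
#
# The YAML config drives the whole experiment (scenario preset, pedigree
# set, replicates, selection strategy, imputers, metrics, association,
# output_dir, base_seed); see ?pedimpute::read_experiment_config.

suppressMessages(library(pedimpute))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 1) stop("usage: Rscript scripts/run_pipeline.R <config.yaml>")
res <- run_pipeline(args[1])
cat("pipeline complete;",
    if (!is.null(res$manifest$files)) length(res$manifest$files) else 0,
    "report files written\n")
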