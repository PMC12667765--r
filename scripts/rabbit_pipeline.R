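#!/usr/bin/env Rscript

# Thin command-line wrapper over the avrabbit pipeline:
#   Rscript scripts/rabbit_pipeline.R simulate --out DIR [--config FILE]
#   Rscript scripts/rabbit_pipeline.R fit      --out DIR [--config FILE]
#   Rscript scripts/rabbit_pipeline.R report   --out DIR
#   Rscript scripts/rabbit_pipeline.R recover  --out DIR [--config FILE]
# Common options: --seed INT, --participants INT, --reps INT,
#                 --strategy NAME, --quadrature-nodes INT

suppressPackageStartupMessages({
  library(avrabbit)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("subcommand required: simulate | fit | report | recover")
cmd <- argv[1]

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "pipeline_out"),
  make_option("--participants", type = "integer", default = NULL),
  make_option("--reps", type = "integer", default = NULL),
  make_option("--strategy", type = "character", default = NULL),
  make_option("--quadrature-nodes", type = "integer", default = NULL,
              dest = "quadrature_nodes")
)), args = argv[-1])

cfg <- load_run_config(opts$config, seed = opts$seed)
if (!is.null(opts$participants)) cfg$n_participants <- opts$participants
if (!is.null(opts$reps)) cfg$design$reps_per_condition <- opts$reps
if (!is.null(opts$strategy)) cfg$strategy <- opts$strategy
if (!is.null(opts$quadrature_nodes)) {
  cfg$fit$quadrature_nodes <- opts$quadrature_nodes
}

switch(cmd,
  simulate = pipeline_simulate(cfg, opts$out),
  fit = pipeline_fit(file.path(opts$out, "trials.csv"), cfg, opts$out),
  report = pipeline_report(opts$out),
  recover = invisible(pipeline_recover(cfg, opts$out)),
  stop("unknown subcommand: ", cmd))

message("done: ", cmd, " -> ", opts$out)
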