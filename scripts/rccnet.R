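#!/usr/bin/env Rscript
# Thin command-line wrapper over rccnet::run_pipeline().
#
# Usage:
#   Rscript scripts/rccnet.R <stage> --outdir DIR [--seed INT] [--config YAML]
#                            [--bundle BUNDLE_YAML]
#   <stage> in: simulate, classify, prioritize, enrich, network, all
#
# Exit codes: 0 ok, 1 validation/input error, 2 runtime error.

suppressMessages({
  library(optparse)
  library(rccnet)
})

args <- commandArgs(trailingOnly = TRUE)
stage <- if (length(args) && !startsWith(args[1], "-")) args[1] else "all"
rest <- if (length(args) && !startsWith(args[1], "-")) args[-1] else args

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL,
    help = "YAML run config (overridden by the flags below)"),
  make_option("--outdir", type = "character", default = NULL),
  make_option("--seed", type = "integer", default = NULL),
  make_option("--bundle", type = "character", default = NULL,
    help = "bundle YAML (skip 'simulate' and use these inputs)")
)), args = rest)

config <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
for (f in c("outdir", "seed", "bundle")) {
  if (!is.null(opts[[f]])) config[[f]] <- opts[[f]]
}

status <- tryCatch({
  run_pipeline(stage, config)
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  if (grepl("missing|required|valid|exist", conditionMessage(e))) 1L else 2L
})
quit(status = status)
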