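#!/usr/bin/env Rscript
# Thin command-line wrapper over yieldclass::run_pipeline(). Usage:
#   Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed <int>] --out <dir>
# Without --config the documented default synthetic campaign is run.

suppressPackageStartupMessages(library(yieldclass))

args <- commandArgs(trailingOnly = TRUE)
get_arg <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
out <- get_arg("--out", NULL)
if (is.null(out)) {
  message("usage: Rscript scripts/run_pipeline.R [--config cfg.yaml] [--seed int] --out dir")
  quit(status = 2)
}
cfg_path <- get_arg("--config", NULL)
seed <- as.integer(get_arg("--seed", "1"))

run <- tryCatch({
  config <- if (is.null(cfg_path)) pipeline_config(seed = seed) else cfg_path
  if (!is.null(cfg_path) && !file.exists(cfg_path)) {
    message("config file not found: ", cfg_path)
    quit(status = 2)  # user error
  }
  if (is.character(config)) {
    run_pipeline(config, out)
  } else {
    config$seed <- seed
    run_pipeline(config, out)
  }
}, error = function(e) {
  message("pipeline failed: ", conditionMessage(e))
  quit(status = 1)  # numerical / stage failure
})
print(run)
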