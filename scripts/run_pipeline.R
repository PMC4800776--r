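#!/usr/bin/env Rscript
# Thin command-line wrapper over coraloptics::run_pipeline().
#
# Usage:
#   Rscript scripts/run_pipeline.R --outdir out [--seed 1]
#       [--stages simulate,absorb,rates,depe,stats,feedback,report]
#       [--config config.yaml]
#
# The optional YAML config holds named overrides of generator_config()
# scalar fields (e.g. n_ramets_per_cell, necrosis_rate, sigma).

suppressPackageStartupMessages(library(coraloptics))
suppressPackageStartupMessages(library(optparse))

parser <- OptionParser(option_list = list(
  make_option("--outdir", type = "character", default = "pipeline_out"),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--stages", type = "character",
              default = "simulate,absorb,rates,depe,stats,feedback,report"),
  make_option("--config", type = "character", default = NULL),
  make_option("--verbose", action = "store_true", default = FALSE)
))
opt <- parse_args(parser)

overrides <- list()
if (!is.null(opt$config)) {
  overrides <- yaml::read_yaml(opt$config)
}
config <- do.call(generator_config, overrides)

man <- run_pipeline(opt$outdir, config = config, seed = opt$seed,
                    stages = strsplit(opt$stages, ",")[[1]])
if (opt$verbose) str(man)
cat("Pipeline complete; manifest at",
    file.path(opt$outdir, "manifest.yaml"), "\n")
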