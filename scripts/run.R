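#!/usr/bin/env Rscript
# Run a scenario end to end and write its artefacts.
#
# Usage:
#   Rscript scripts/run.R [--triplets N] [--tails N] [--seed N]
#                         [--config cfg.txt] [-o outdir]
#
# Writes model.pdb, report.json, steps.tsv and contacts.tsv to the output
# directory (default: results/run).

suppressPackageStartupMessages(library(filamentforge))

args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i)) return(default)
  if (i == length(args)) stop("missing value for ", flag, call. = FALSE)
  args[i + 1]
}

triplets <- as.integer(opt("--triplets", "2"))
tails <- as.integer(opt("--tails", "6"))
seed <- as.integer(opt("--seed", "1"))
cfg_path <- opt("--config", NA)
outdir <- opt("-o", "results/run")

config <- if (is.na(cfg_path)) fil_defaults() else read_fil_config(cfg_path)
spec <- scenario_spec(n_triplets = triplets, tail_bp_5p = tails,
                      tail_bp_3p = tails, seed = seed)
rep <- run_scenario(spec, config = config, outdir = outdir)
print(rep)
cat("wrote", file.path(outdir, "model.pdb"), "and report.json/steps.tsv/contacts.tsv\n")
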