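#!/usr/bin/env Rscript
# Stage 5 — one-call reproduction. Runs the orchestrated pipeline
# (simulate -> impute -> fit -> effects -> heterogeneity) from the same
# master seed and writes the full report bundle, including report.md, under
# results/full_run/. Stages 1-4 exist to make each step inspectable; this
# stage shows the end-to-end entry point and doubles as a reproducibility
# check of the orchestrator.

suppressPackageStartupMessages(library(gformulaHTE))
master_seed <- 1L

cfg <- run_config(
  generator = generation_config(),
  library = default_library(),
  V = 10, n_boot = 200, fast_boot = TRUE,
  seed = master_seed)

res <- run_emulation(cfg, out_dir = file.path("results", "full_run"))

cat(readLines(file.path("results", "full_run", "report.md")), sep = "\n")
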