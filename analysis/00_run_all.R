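#!/usr/bin/env Rscript
# One-shot driver: runs the whole pipeline through run_pipeline() into
# results/pipeline/ (equivalent to stages 01-04 with a smaller bootstrap),
# then executes the numbered stage scripts in order.

suppressPackageStartupMessages(library(triocomp))

run_pipeline(trio_config(), "results/pipeline", m = 10,
             p_grid = c(0, 0.01, 0.02, 0.05, 0.10, 0.15, 0.20), B = 0)

for (script in c("analysis/01_simulate.R", "analysis/02_descriptives.R",
                 "analysis/03_impute_fit.R", "analysis/04_nonpaternity.R")) {
  message("== ", script, " ==")
  source(script, echo = FALSE)
}
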