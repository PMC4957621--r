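#!/usr/bin/env Rscript
# Stage 1: generate the synthetic parent-offspring cohort.
#
# Emulates the study's statistical structure: 511 trios, offspring aged
# 5-22, assortatively mated parents (realized mother-father BMI correlation
# ~0.143), sex-specific transmission of parental BMI to offspring BMI/FMI/
# LMI z-scores, raw 4C measurements constructed to be self-consistent with
# the body-composition equations, and 14% MCAR paternal missingness.

suppressPackageStartupMessages(library(triocomp))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- trio_config()                 # defaults = study calibration
sim <- simulate_trios(cfg)

write_trios(sim$trios, file.path(out, "trios.csv"))
write_truth(sim$truth, cfg, file.path(out, "truth.csv"))
write_lms_reference(sim$ref, file.path(out, "lms_reference_synthetic.csv"))

message(sprintf("simulated %d trios (seed %d)", cfg$n_trios, cfg$seed))
message(sprintf("  paternal data missing: %.1f%%",
                100 * mean(is.na(sim$trios$father_weight_kg))))
message(sprintf("  male offspring: %d", sum(sim$trios$sex == "M")))
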