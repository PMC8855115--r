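#!/usr/bin/env Rscript
# Stage 1: generate the synthetic microscopy experiment.
#
# Two glioma-like cell lines (9L-like and a more radiosensitive C6-like
# preset) x six fractionation schedules (16 Gy as 2x8/3x5.3/4x4; 20 Gy as
# 2x10/3x6.7/4x5, all 24 h apart) x 40 replicate wells, seeded over a 10x
# density range, imaged every 4-6 h to 330 h, with 21% multiplicative
# measurement noise -- after the 75% split this gives ~240 training curves
# per line, matching the order of the real experiment's training sets
# (a scale that matters: with only tens of curves the small-sample AICc
# penalty makes the no-early-death daughter win, since the early-death term
# sits below the 21% noise floor). Writes the curves and repair-rate tables
# consumed by the later stages.

suppressPackageStartupMessages(library(fracdyn))

seed <- 20260918
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- default_truth(generating_model_id = 3,
                       replicates_per_condition = 40,
                       noise_cv = 0.21,
                       dt = 0.1)  # generator Euler step, shared by stages 2-4

ds <- generate_dataset(truth, seed = seed)
message(sprintf("generated %d curves (%d lines x 6 schedules x %d replicates)",
                length(ds$curves), length(truth$cell_lines),
                truth$replicates_per_condition))

write_curves(ds$curves, file.path(out, "curves.csv"))
for (line in names(truth$cell_lines))
  write_repair_kinetics(truth$cell_lines[[line]]$kinetics,
                        file.path(out, sprintf("repair_kinetics_%s.csv", line)))

# record the generating truth so stages 3-4 can score recovery
truth_rec <- lapply(truth$cell_lines, function(cl) {
  rad <- cl$rad
  list(growth = unclass(cl$growth),
       rad = c(rad[names(rad) != "k_ps"], list(k_ps = as.list(rad$k_ps))))
})
jsonlite::write_json(list(seed = seed, generating_model = 3,
                          noise_cv = truth$noise_cv,
                          cell_lines = truth_rec),
                     file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote ", out, "/curves.csv and truth.json")
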