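#!/usr/bin/env Rscript
# Stage 4: forward prediction on the held-out 25% and error analysis.
#
# Every validation well is predicted from only its initial confluence and
# schedule using the line's single calibrated parameter set; agreement is
# scored per replicate with the Pearson (PCC) and Lin concordance (CCC)
# coefficients and summarized mean +/- SE per condition, per total dose,
# and overall -- the synthetic analogue of the experiment's error table.

suppressPackageStartupMessages(library(fracdyn))

seed <- 20260918
data_dir <- "results/data"
out <- "results/validation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

curves <- read_curves(file.path(data_dir, "curves.csv"))
sp <- train_validation_split(curves, fraction = 0.75, seed = seed + 1)
lines <- unique(vapply(curves, function(cv) cv$cell_line, ""))
spec <- model_family()[["model_3"]]

calibs <- setNames(lapply(lines, function(line) {
  tr <- Filter(function(cv) cv$cell_line == line, sp$training)
  calibrate_global(spec, tr,
                   setNames(list(synthetic_growth_params(line)), line),
                   synthetic_repair_kinetics(line),
                   n_starts = 8, seed = seed + 3, dt = 0.1,
                   control = list(maxfev = 600))
}), lines)

vm <- validate_predictions(calibs, sp$validation)
print(vm)

utils::write.csv(vm$per_condition, file.path(out, "per_condition.csv"),
                 row.names = FALSE)
utils::write.csv(vm$per_total_dose, file.path(out, "per_total_dose.csv"),
                 row.names = FALSE)
utils::write.csv(vm$per_replicate, file.path(out, "per_replicate.csv"),
                 row.names = FALSE)

# example prediction export with delta-method bands for one held-out well
cv <- sp$validation[[1L]]
pr <- predict_confluence(calibs[[cv$cell_line]], cv$N0, cv$schedule_id,
                         cv$times, cell_line = cv$cell_line,
                         interval = "prediction")
utils::write.csv(cbind(replicate_id = cv$replicate_id, pr,
                       measured = cv$confluence),
                 file.path(out, "example_prediction.csv"), row.names = FALSE)
message("wrote ", out, "/per_condition.csv (+ per_total_dose, per_replicate)")
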