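#' Run configuration
#'
#' Loads a JSON run configuration for [run_pipeline()]. Recognized fields:
#' `curves_csv`, `kinetics_csv` (input paths; omitted when `generate` is
#' given), `generate` (list: `generating_model_id`, `replicates_per_condition`,
#' `noise_cv`, `heterogeneity_cv`, `horizon`, `n0_range`, `cell_lines` --
#' names of built-in synthetic presets), `model_id` (default 3),
#' `run_selection` (default FALSE), `split` (`fraction`, `n_density_strata`),
#' `calibration` (`n_starts`, `dt`, `maxfev`), `level`.
#' Referenced files must exist at load time.
#'
#' @param path JSON file path.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("curves_csv", "kinetics_csv")) {
    if (!is.null(cfg[[f]])) {
      cfg[[f]] <- file.path(dirname(path), cfg[[f]])
      if (!file.exists(cfg[[f]]))
        stop_fd("configured file does not exist: ", cfg[[f]],
                class = "fracdyn_config_error")
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

config_from_list <- function(cfg) structure(cfg, class = c("run_config", "list"))

truth_from_config <- function(gen) {
  args <- list(generating_model_id = gen$generating_model_id %||% 3L)
  for (f in c("replicates_per_condition", "noise_cv", "heterogeneity_cv",
              "horizon", "dt"))
    if (!is.null(gen[[f]])) args[[f]] <- gen[[f]]
  if (!is.null(gen$n0_range)) args$n0_range <- as.numeric(gen$n0_range)
  truth <- do.call(default_truth, args)
  if (!is.null(gen$cell_lines))
    truth$cell_lines <- truth$cell_lines[as.character(gen$cell_lines)]
  truth
}

#' Run the full analysis pipeline
#'
#' Stages, in experiment order: obtain curves (generate synthetically or
#' read from CSV), stratified train/validation split, optional AICc model
#' selection over the eight-member family, global calibration of the chosen
#' model per cell line, and validation (PCC/CCC) on the held-out curves.
#' All artifacts are written under `out_dir` as CSV/JSON, every artifact
#' embeds the master seed, and a manifest records the config hash -- output
#' is byte-reproducible for a fixed (config, seed).
#'
#' @param config a `run_config` (from [read_run_config()]) or a plain list.
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return (invisibly) list with the split, selection (or NULL),
#'   calibrations, and validation metrics.
#' @export
run_pipeline <- function(config, seed, out_dir, quiet = FALSE) {
  t_start <- proc.time()[["elapsed"]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- unclass(config)
  say <- function(...) if (!quiet) message(sprintf(...))

  # config hash for provenance (hash of the canonical JSON serialization)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)

  model_id <- cfg$model_id %||% 3L
  level <- cfg$level %||% 0.95
  cal_cfg <- cfg$calibration %||% list()
  dt <- cal_cfg$dt %||% 0.01
  n_starts <- cal_cfg$n_starts %||% 4L
  control <- list(maxfev = cal_cfg$maxfev %||% 2000)

  # stage 1: data
  if (!is.null(cfg$generate)) {
    truth <- truth_from_config(cfg$generate)
    say("generate: %d cell lines x %d schedules x %d replicates (seed %d)",
        length(truth$cell_lines), length(truth$schedules),
        truth$replicates_per_condition, seed)
    ds <- generate_dataset(truth, seed = seed)
    curves <- ds$curves
    growth <- lapply(truth$cell_lines, function(cl) cl$growth)
    kinetics_by_line <- lapply(truth$cell_lines, function(cl) cl$kinetics)
    write_curves(curves, file.path(out_dir, "curves.csv"))
    write_repair_kinetics(kinetics_by_line[[1L]],
                          file.path(out_dir, "repair_kinetics.csv"))
  } else {
    curves <- read_curves(cfg$curves_csv)
    kin <- read_repair_kinetics(cfg$kinetics_csv)
    lines <- unique(vapply(curves, function(cv) cv$cell_line, ""))
    growth <- setNames(lapply(lines, synthetic_growth_params), lines)
    kinetics_by_line <- setNames(rep(list(kin), length(lines)), lines)
  }
  schedules <- schedule_presets()

  # stage 2: split
  split_cfg <- cfg$split %||% list()
  sp <- train_validation_split(curves,
                               fraction = split_cfg$fraction %||% 0.75,
                               seed = child_seed(seed, 1),
                               n_density_strata = split_cfg$n_density_strata %||% 2L)
  say("split: %d training / %d validation curves",
      length(sp$training), length(sp$validation))

  by_line <- split(sp$training,
                   vapply(sp$training, function(cv) cv$cell_line, ""))
  lines <- names(by_line)

  # stage 3: optional model selection on the training set
  selection <- NULL
  if (isTRUE(cfg$run_selection)) {
    family <- model_family(k_ps_doses = sort(unique(vapply(
      sp$training, function(cv)
        resolve_schedule(cv$schedule_id, schedules)$total_dose, 0))))
    selection <- lapply(lines, function(ln) {
      say("selection (%s): fitting 8 candidate models", ln)
      select_model(by_line[[ln]], family, growth[ln], kinetics_by_line[[ln]],
                   schedules, n_starts = n_starts,
                   seed = child_seed(seed, 2), dt = dt, control = control)
    })
    names(selection) <- lines
    model_id <- selection[[1L]]$selected_id
    sel_out <- lapply(selection, function(s)
      list(table = s$table, selected_id = s$selected_id))
    jsonlite::write_json(list(seed = seed, config_hash = cfg_hash,
                              selection = sel_out),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  # stage 4: calibration of the chosen model, per cell line
  spec <- model_family(k_ps_doses = sort(unique(vapply(
    sp$training, function(cv)
      resolve_schedule(cv$schedule_id, schedules)$total_dose,
    0))))[[paste0("model_", model_id)]]
  calibs <- lapply(lines, function(ln) {
    say("calibrate (%s): model %d, %d curves", ln, spec$id,
        length(by_line[[ln]]))
    calibrate_global(spec, by_line[[ln]], growth[ln], kinetics_by_line[[ln]],
                     schedules, n_starts = n_starts,
                     seed = child_seed(seed, 3), dt = dt, level = level,
                     control = control)
  })
  names(calibs) <- lines
  cal_out <- lapply(calibs, function(cb)
    list(model_id = cb$spec$id, estimates = as.list(cb$estimates),
         se = as.list(cb$se),
         ci_lower = as.list(cb$ci[, "lower"]),
         ci_upper = as.list(cb$ci[, "upper"]),
         rss = cb$rss, m = cb$m, p = cb$p, converged = cb$converged,
         collinear_pairs = cb$collinear_pairs))
  jsonlite::write_json(list(seed = seed, config_hash = cfg_hash,
                            calibration = cal_out),
                       file.path(out_dir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # stage 5: validation on held-out curves
  metrics <- validate_predictions(calibs, sp$validation)
  vt <- metrics$per_condition
  vt$seed <- seed
  utils::write.csv(vt, file.path(out_dir, "validation.csv"),
                   row.names = FALSE, quote = FALSE)

  jsonlite::write_json(
    list(seed = seed, config_hash = cfg_hash, model_id = model_id,
         n_training = length(sp$training),
         n_validation = length(sp$validation),
         artifacts = sort(setdiff(list.files(out_dir), "manifest.json"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("pipeline done in %.1f s", proc.time()[["elapsed"]] - t_start)
  invisible(list(split = sp, selection = selection, calibrations = calibs,
                 validation = metrics))
}
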