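#' Ground-truth configuration for the synthetic experiment
#'
#' Describes the world the generator draws from: per-cell-line growth
#' parameters, radiation parameters, and repair kinetics; the generating
#' model; measurement noise and replicate heterogeneity; and the
#' experimental design (schedules, sampling, seeding densities, replicate
#' counts). Defaults emulate the in vitro microscopy experiment: six
#' schedules (16 or 20 Gy total in 2-4 daily fractions), sampling every
#' 4-6 hr to 330 hr, seeding densities spanning a 10x range, and 21%
#' multiplicative measurement noise (the reported segmentation error).
#'
#' @param cell_lines named list; each entry a list with elements `growth`
#'   ([growth_params()]), `rad` ([radiation_params()]), and `kinetics`
#'   ([repair_kinetics()]).
#' @param generating_model [model_spec()] used to simulate truth (default
#'   family model 3).
#' @param schedules named list of [dose_schedule()]s (default the six
#'   presets).
#' @param noise_cv multiplicative Gaussian measurement noise CV
#'   (default 0.21).
#' @param heterogeneity_cv relative SD of per-replicate lognormal
#'   multipliers applied to the death-rate parameters (default 0: the
#'   calibration model assumes shared parameters).
#' @param interval_range sampling interval range in hr (default `c(4, 6)`).
#' @param horizon experiment length in hr (default 330).
#' @param n0_range seeding confluence range (default `c(0.03, 0.3)`,
#'   a 10x span), drawn log-uniformly.
#' @param replicates_per_condition replicates per (cell line, schedule).
#' @param media_change optional list `list(period =, loss_range =)`:
#'   every `period` hr the attached population loses a uniformly drawn
#'   fraction of cells (media-refresh artifact; `NULL` = off, the default).
#' @param dt Euler step for truth simulation (hr).
#' @param gate_sharpness tanh gate sharpness.
#' @return object of class `truth_config`.
#' @export
truth_config <- function(cell_lines,
                         generating_model = model_family()[["model_3"]],
                         schedules = schedule_presets(),
                         noise_cv = 0.21, heterogeneity_cv = 0,
                         interval_range = c(4, 6), horizon = 330,
                         n0_range = c(0.03, 0.3),
                         replicates_per_condition = 12,
                         media_change = NULL,
                         dt = 0.01, gate_sharpness = 1) {
  if (noise_cv < 0 || heterogeneity_cv < 0)
    stop_fd("CVs must be >= 0", class = "fracdyn_config_error")
  for (cl in names(cell_lines)) {
    th <- cell_lines[[cl]]$growth$theta
    if (n0_range[1L] <= 0 || n0_range[2L] >= th)
      stop_fd("n0_range must lie within (0, theta) for cell line ", cl,
              class = "fracdyn_config_error")
  }
  last_frac <- max(vapply(schedules, function(s) max(s$fraction_times), 0))
  if (horizon <= last_frac)
    stop_fd("horizon must exceed the last fraction time",
            class = "fracdyn_config_error")
  structure(list(cell_lines = cell_lines,
                 generating_model = generating_model,
                 schedules = schedules, noise_cv = noise_cv,
                 heterogeneity_cv = heterogeneity_cv,
                 interval_range = interval_range, horizon = horizon,
                 n0_range = n0_range,
                 replicates_per_condition = replicates_per_condition,
                 media_change = media_change, dt = dt,
                 gate_sharpness = gate_sharpness),
            class = "truth_config")
}

#' Default synthetic radiation parameters
#'
#' Ground-truth radiation parameters are not published (the calibrated
#' values are shown only graphically), so these synthetic defaults are
#' chosen a priori to satisfy the qualitative constraints the experiment
#' reports: late (accumulation) death dominates early (acute) death; the
#' efficacy decay `r` places peak late death days after a fraction and is
#' shared between lines; C6 is the radiosensitive preset (larger death and
#' conversion rates than 9L); and trajectories rise, decline after
#' treatment, and regrow late under the weaker schedules. Entries outside a
#' given model's active set are simply ignored by that model.
#'
#' @param cell_line `"9L"` or `"C6"`.
#' @return a [radiation_params()] object.
#' @export
synthetic_radiation_params <- function(cell_line = c("9L", "C6")) {
  cell_line <- match.arg(cell_line)
  sens <- if (cell_line == "C6") 1.8 else 1
  radiation_params(
    alpha_acute_N = 6,
    k_acute_D = 0.006 * sens,
    k_acute_N = 0.03 * sens,
    alpha_accum_N = 3,
    k_accum_D = 2.2e-4 * sens,
    k_accum_N = 0.015 * sens,
    r = 0.02,
    k_ps = c("16" = 0.05, "20" = 0.08) * sens)
}

#' Default synthetic truth configuration
#'
#' Two cell lines (9L, C6) with the synthetic growth, radiation and repair
#' presets, generating from family model `generating_model_id`.
#'
#' @param generating_model_id model id 1-8 (default 3, the selected model).
#' @param ... passed to [truth_config()].
#' @return a [truth_config()].
#' @export
default_truth <- function(generating_model_id = 3L, ...) {
  cl <- function(line) list(growth = synthetic_growth_params(line),
                            rad = synthetic_radiation_params(line),
                            kinetics = synthetic_repair_kinetics(line))
  truth_config(
    cell_lines = list(`9L` = cl("9L"), C6 = cl("C6")),
    generating_model =
      model_family()[[paste0("model_", generating_model_id)]],
    ...)
}

# child seed derivation, kept below 2^31
child_seed <- function(seed, i) (as.numeric(seed) * 7919 + 104729 * i) %% 2147483647

apply_heterogeneity <- function(rad, cv) {
  if (cv == 0) return(rad)
  sdlog <- sqrt(log(1 + cv^2))
  death_par <- c("k_acute_D", "k_acute_N", "k_accum_D", "k_accum_N")
  for (nm in death_par) {
    mult <- stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    rad[[nm]] <- rad[[nm]] * mult
  }
  rad
}

#' Generate one synthetic replicate curve
#'
#' Simulates the generating model for one well (with optional per-replicate
#' lognormal heterogeneity on the death rates), samples it at times drawn
#' cumulatively with uniform 4-6 hr spacing from 0 to the horizon, applies
#' multiplicative Gaussian noise truncated at zero, and (optionally)
#' media-change cell-loss jumps, simulated as state discontinuities.
#'
#' @param truth a [truth_config()].
#' @param cell_line name of a configured cell line.
#' @param schedule_id id of a configured schedule.
#' @param N0 seeding confluence, inside `truth$n0_range`.
#' @param seed integer seed (same seed, same curve).
#' @param replicate_id label for the curve.
#' @return a [confluence_curve()]; attributes `true_confluence` (noise-free
#'   values at the sampled times) and `true_N0`.
#' @export
generate_replicate <- function(truth, cell_line, schedule_id, N0, seed,
                               replicate_id = sprintf("%s_%s_s%d", cell_line,
                                                      schedule_id, seed)) {
  stopifnot(inherits(truth, "truth_config"))
  if (N0 < truth$n0_range[1L] || N0 > truth$n0_range[2L])
    stop_fd("N0 outside configured seeding range", class = "fracdyn_domain_error")
  cl <- truth$cell_lines[[cell_line]]
  if (is.null(cl))
    stop_fd("unknown cell line ", cell_line, class = "fracdyn_config_error")
  sched <- resolve_schedule(schedule_id, truth$schedules)

  withr::with_seed(seed, {
    rad <- apply_heterogeneity(cl$rad, truth$heterogeneity_cv)

    # sampling grid: cumulative uniform intervals from 0
    n_max <- ceiling(truth$horizon / truth$interval_range[1L]) + 1L
    gaps <- runif(n_max, truth$interval_range[1L], truth$interval_range[2L])
    times <- c(0, cumsum(gaps))
    times <- times[times <= truth$horizon]

    sim <- function(t0, state, out_times, horizon) {
      simulate_confluence(truth$generating_model, cl$growth, rad, sched,
                          N0, cl$kinetics, output_times = out_times,
                          dt = truth$dt, horizon = horizon,
                          gate_sharpness = truth$gate_sharpness,
                          init_state = state, t0 = t0)
    }
    if (is.null(truth$media_change)) {
      traj <- sim(0, c(N0, 0), times, max(times))
    } else {
      # piecewise simulation with a state jump at each media change
      mc_times <- seq(truth$media_change$period, max(times),
                      by = truth$media_change$period)
      bounds <- c(0, mc_times, max(times))
      state <- c(N0, 0)
      pieces <- list()
      for (k in seq_len(length(bounds) - 1L)) {
        lo <- bounds[k]; hi <- bounds[k + 1L]
        keep <- times >= lo & (if (k == length(bounds) - 1L) times <= hi
                               else times < hi)
        seg <- sim(lo, state, unique(c(times[keep], hi)), hi)
        end <- seg[nrow(seg), ]
        pieces[[k]] <- seg[seg$time %in% times[keep], , drop = FALSE]
        loss <- runif(1, truth$media_change$loss_range[1L],
                      truth$media_change$loss_range[2L])
        state <- c(end$N_p, end$N_s) * (1 - loss)
      }
      traj <- do.call(rbind, pieces)
      traj <- traj[!duplicated(traj$time), , drop = FALSE]
    }
    true_vals <- traj$N_total

    noisy <- if (truth$noise_cv > 0)
      pmax(true_vals * (1 + truth$noise_cv * rnorm(length(true_vals))), 0)
    else true_vals
    noisy[1L] <- max(noisy[1L], 1e-6)  # N0 must stay positive

    cv <- confluence_curve(replicate_id, cell_line, sched$id, traj$time, noisy)
    attr(cv, "true_confluence") <- true_vals
    attr(cv, "true_N0") <- N0
    attr(cv, "realized_rad") <- rad
    cv
  })
}

#' Generate a full synthetic dataset
#'
#' Full factorial over configured cell lines x schedules x replicates, with
#' seeding confluences drawn log-uniformly from `truth$n0_range` per
#' replicate. Deterministic under the master seed.
#'
#' @param truth a [truth_config()].
#' @param seed master seed.
#' @return object of class `synthetic_dataset`: `curves` (named list),
#'   `design` (data.frame with true N0 and child seed per replicate),
#'   `truth`, `seed`.
#' @export
generate_dataset <- function(truth, seed) {
  stopifnot(inherits(truth, "truth_config"))
  if (truth$replicates_per_condition < 1L)
    stop_fd("need >= 1 replicate per condition", class = "fracdyn_config_error")
  grid <- expand.grid(rep = seq_len(truth$replicates_per_condition),
                      schedule_id = names(truth$schedules),
                      cell_line = names(truth$cell_lines),
                      stringsAsFactors = FALSE)
  n0s <- withr::with_seed(seed, {
    exp(runif(nrow(grid), log(truth$n0_range[1L]), log(truth$n0_range[2L])))
  })
  curves <- vector("list", nrow(grid))
  design <- grid
  design$true_N0 <- n0s
  design$child_seed <- vapply(seq_len(nrow(grid)), function(i)
    child_seed(seed, i), 0)
  design$replicate_id <- sprintf("%s_%s_r%03d", grid$cell_line,
                                 grid$schedule_id, grid$rep)
  for (i in seq_len(nrow(grid))) {
    curves[[i]] <- generate_replicate(truth, grid$cell_line[i],
                                      grid$schedule_id[i], n0s[i],
                                      seed = design$child_seed[i],
                                      replicate_id = design$replicate_id[i])
  }
  names(curves) <- design$replicate_id
  structure(list(curves = curves, design = design, truth = truth,
                 seed = seed),
            class = "synthetic_dataset")
}

#' Stratified train/validation split
#'
#' Randomly assigns `round(fraction * n)` replicates of each stratum
#' (cell line x schedule x seeding-density stratum) to training, the rest
#' to validation; every treatment condition is therefore equally
#' represented in the training set. Density strata are quantile bins of
#' log N0 within each condition. A stratum with a single replicate goes to
#' training with a warning.
#'
#' @param dataset a [generate_dataset()] result, or a plain list of curves.
#' @param fraction training fraction (default 0.75).
#' @param seed integer seed.
#' @param n_density_strata number of seeding-density bins (default 2).
#' @return list with `training` and `validation` (named curve lists,
#'   disjoint and exhaustive).
#' @export
train_validation_split <- function(dataset, fraction = 0.75, seed = 1,
                                   n_density_strata = 2L) {
  curves <- if (inherits(dataset, "synthetic_dataset")) dataset$curves
            else dataset
  curves <- sort_curves(curves)
  names(curves) <- vapply(curves, function(cv) cv$replicate_id, "")
  info <- data.frame(
    idx = seq_along(curves),
    cell_line = vapply(curves, function(cv) cv$cell_line, ""),
    schedule_id = vapply(curves, function(cv) cv$schedule_id, ""),
    n0 = vapply(curves, function(cv) cv$N0, 0))
  cond <- paste(info$cell_line, info$schedule_id)
  stratum <- cond
  if (n_density_strata > 1L) {
    for (cc in unique(cond)) {
      sel <- cond == cc
      qs <- stats::quantile(log(info$n0[sel]),
                            probs = seq(0, 1, length.out = n_density_strata + 1L))
      bin <- cut(log(info$n0[sel]), unique(qs), include.lowest = TRUE,
                 labels = FALSE)
      stratum[sel] <- paste(cc, bin)
    }
  }
  # allocate round(fraction * n) training replicates per *condition*, then
  # spread them over that condition's density strata by largest remainder
  # (plain per-stratum rounding can drift from the condition-level count)
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(unique(cond), function(cc) {
      strata <- split(info$idx[cond == cc], stratum[cond == cc])
      sizes <- lengths(strata)
      n <- sum(sizes)
      if (n < 2L) {
        warning("stratum with a single replicate assigned to training")
        return(unlist(strata, use.names = FALSE))
      }
      target <- round(fraction * n)
      exact <- fraction * sizes
      take <- floor(exact)
      rem <- target - sum(take)
      if (rem > 0) {
        ord <- order(exact - take, decreasing = TRUE)
        take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
      } else if (rem < 0) {
        ord <- order(exact - take)
        drop_ <- ord[seq_len(-rem)]
        take[drop_] <- take[drop_] - 1L
      }
      take <- pmin(pmax(take, 0L), sizes)
      unlist(lapply(seq_along(strata), function(k) {
        if (sizes[k] == 1L) {
          warning("stratum with a single replicate assigned to training")
          return(strata[[k]])
        }
        # subset by index: sample(x, n) on a length-1 x would misfire
        strata[[k]][sample.int(sizes[k], take[k])]
      }), use.names = FALSE)
    }), use.names = FALSE)
  })
  train_idx <- sort(unique(train_idx))
  list(training = curves[train_idx],
       validation = curves[setdiff(info$idx, train_idx)])
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d curves (%d cell lines x %d schedules x %d replicates), master seed %d\n",
              length(x$curves), length(x$truth$cell_lines),
              length(x$truth$schedules), x$truth$replicates_per_condition,
              x$seed))
  invisible(x)
}
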