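#' Corrected Akaike information criterion
#'
#' `AICc = n*ln(RSS/n) + 2p + (2p^2 + 2p)/(n - p - 1)`, with `n` the sample
#' count (by convention here, the number of confluence curves), `RSS` the
#' total squared residual, and `p` the free-parameter count.
#'
#' @param n sample count (> p + 1).
#' @param rss residual sum of squares (> 0).
#' @param p number of free parameters (>= 0).
#' @return the AICc score.
#' @examples
#' aicc(100, 100, 6)  # 12 + 84/93
#' @export
aicc <- function(n, rss, p) {
  if (any(n <= p + 1))
    stop_fd("AICc correction needs n > p + 1", class = "fracdyn_domain_error")
  if (any(rss <= 0))
    stop_fd("rss must be > 0", class = "fracdyn_domain_error")
  n * log(rss / n) + 2 * p + (2 * p^2 + 2 * p) / (n - p - 1)
}

#' Akaike weights
#'
#' Standard form: `Delta_i = AICc_i - min(AICc)`,
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)`, so the best (lowest-
#' score) model receives the largest weight, and the weight ratio of two
#' models equals `exp((AICc_b - AICc_a)/2)`. A nonstandard `"printed"`
#' variant (`delta_i = (AICc_i - AICc_min)/AICc_min`, weights proportional
#' to `exp(+delta_i)`) is provided for comparison only; note it ranks models
#' in the opposite order whenever scores are positive.
#'
#' @param scores numeric vector of at least two finite AICc scores.
#' @param variant `"standard"` (default) or `"printed"`.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(scores, variant = c("standard", "printed")) {
  variant <- match.arg(variant)
  if (length(scores) < 2L || any(!is.finite(scores)))
    stop_fd("need >= 2 finite scores", class = "fracdyn_domain_error")
  if (variant == "standard") {
    delta <- scores - min(scores)
    w <- exp(-delta / 2)
  } else {
    delta <- (scores - min(scores)) / min(scores)
    w <- exp(delta)
  }
  w / sum(w)
}

#' AICc model selection over the candidate family
#'
#' Calibrates each family member globally on the training set, scores it
#' with [aicc()] (by default `n` = number of curves, `RSS` = total squared
#' residual over all time points; `n_def = "observations"` uses the total
#' observation count instead), and returns scores, Akaike weights and the
#' selected id (lowest AICc; ties go to the model with fewer parameters).
#'
#' @inheritParams calibrate_global
#' @param family list of [model_spec()]s, typically [model_family()].
#' @param n_def `"curves"` (default) or `"observations"`.
#' @param warm_start fit the full model (family member with `early` and
#'   `late` both `"full"`) first and seed every other member with its
#'   mapped estimates (reduced coefficients matched at the training set's
#'   mean density and dose). Guards the reduced models against losing to
#'   the full model through optimization failure rather than fit quality.
#'   Default TRUE.
#' @return object of class `selection_result`: `table` (data.frame with
#'   `model_id`, `p`, `n`, `rss`, `aicc`, `weight`, `converged`),
#'   `selected_id`, `fits` (the per-model [calibrate_global()] results),
#'   `seed`.
#' @export
select_model <- function(curves, family, growth_by_cell_line, kinetics,
                         schedules = schedule_presets(),
                         n_def = c("curves", "observations"),
                         init = NULL, n_starts = 4, seed = 1, dt = 0.01,
                         gate_sharpness = 1, control = list(),
                         warm_start = TRUE) {
  n_def <- match.arg(n_def)
  if (!length(curves)) stop_fd("empty training set", class = "fracdyn_data_error")

  full_idx <- which(vapply(family, function(s)
    s$early == "full" && s$late == "full" && s$senescence, TRUE))[1L]
  full_fit <- NULL
  mean_n0 <- mean(vapply(curves, function(cv) cv$N0, 0))
  mean_dpf <- mean(vapply(curves, function(cv)
    resolve_schedule(cv$schedule_id, schedules)$dose_per_fraction, 0))

  fit_one <- function(spec, extra_init) {
    st <- if (!is.null(init)) init[spec$free_parameter_names] else NULL
    cb <- calibrate_global(spec, curves, growth_by_cell_line, kinetics,
                           schedules, init = st, n_starts = n_starts,
                           seed = seed, dt = dt,
                           gate_sharpness = gate_sharpness, control = control)
    if (!is.null(extra_init)) {
      cb2 <- calibrate_global(spec, curves, growth_by_cell_line, kinetics,
                              schedules, init = extra_init, n_starts = 1,
                              seed = seed, dt = dt,
                              gate_sharpness = gate_sharpness,
                              control = control)
      if (cb2$rss < cb$rss) cb <- cb2
    }
    cb
  }

  if (warm_start && length(full_idx) && !is.na(full_idx)) {
    full_fit <- fit_one(family[[full_idx]], NULL)
  }
  fits <- lapply(seq_along(family), function(i) {
    spec <- family[[i]]
    if (!is.null(full_fit) && i == full_idx) return(full_fit)
    extra <- if (!is.null(full_fit))
      warm_init(spec, full_fit$estimates, mean_n0, mean_dpf) else NULL
    fit_one(spec, extra)
  })
  names(fits) <- names(family)
  n <- if (n_def == "curves") length(curves) else fits[[1L]]$m
  tab <- do.call(rbind, lapply(fits, function(f) {
    # numerically exact fits can reach RSS == 0; floor keeps log finite
    # (the floored model still wins by a huge margin)
    data.frame(model_id = f$spec$id, p = f$p, n = n,
               rss = f$rss,
               aicc = aicc(n, max(f$rss, 1e-300), f$p),
               converged = f$converged)
  }))
  rownames(tab) <- NULL
  tab$weight <- akaike_weights(tab$aicc)
  best <- which(tab$aicc == min(tab$aicc))
  if (length(best) > 1L) best <- best[which.min(tab$p[best])]
  structure(list(table = tab, selected_id = tab$model_id[best],
                 fits = fits, seed = seed, n_def = n_def),
            class = "selection_result")
}

# map full-model estimates onto a reduced spec's free parameters: reduced
# death coefficients are matched to the full coefficient at the training
# set's mean density/dose, so the warm start reproduces a comparable fit
warm_init <- function(spec, est_full, mean_n0, mean_dpf) {
  gf <- function(nm) if (nm %in% names(est_full)) est_full[[nm]] else 0
  ka_full <- (gf("alpha_acute_N") * mean_n0 + 1) * gf("k_acute_D") * mean_dpf
  kacc_full <- (gf("alpha_accum_N") * mean_n0 + 1) * gf("k_accum_D") * mean_dpf
  out <- setNames(numeric(length(spec$free_parameter_names)),
                  spec$free_parameter_names)
  for (nm in names(out)) {
    out[nm] <- switch(nm,
      alpha_acute_N = gf("alpha_acute_N"),
      k_acute_D = if (spec$early == "dose_only")
        ka_full / mean_dpf else gf("k_acute_D"),
      k_acute_N = ka_full / mean_n0,
      alpha_accum_N = gf("alpha_accum_N"),
      k_accum_D = if (spec$late == "dose_only")
        kacc_full / mean_dpf else gf("k_accum_D"),
      k_accum_N = kacc_full / mean_n0,
      r = gf("r"),
      gf(nm))  # k_ps_* carry over
  }
  pmax(out, 1e-10)
}

#' @export
print.selection_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected model:", x$selected_id, "\n")
  invisible(x)
}
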