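#' Forward prediction with delta-method bands
#'
#' Simulates total confluence at the calibrated estimates for a new initial
#' confluence and schedule, with pointwise uncertainty from first-order
#' (delta-method) propagation of the parameter covariance: at each time the
#' half-width is `t_quantile(level, m-p) * sqrt(g' Cov g)` where `g` is the
#' central finite-difference gradient of predicted confluence with respect
#' to the free parameters (relative step 1e-6). `interval = "prediction"`
#' additionally adds the residual variance `s^2` inside the square root
#' (an observation-level band, for comparison with noisy measurements).
#'
#' @param calib a [calibrate_global()] result.
#' @param N0 initial confluence of the predicted well.
#' @param schedule a [dose_schedule()] or preset id.
#' @param times output times (hr).
#' @param cell_line cell line whose growth parameters to use (defaults to
#'   the only line in the calibration).
#' @param level band level (default 0.95).
#' @param interval `"confidence"` (band on the predicted mean, default) or
#'   `"prediction"` (adds residual variance).
#' @return data.frame of class `fd_prediction` with `time`, `fit`, `lwr`,
#'   `upr`, `half_width`.
#' @export
predict_confluence <- function(calib, N0, schedule, times,
                               cell_line = names(calib$growth_by_cell_line)[1L],
                               level = calib$level,
                               interval = c("confidence", "prediction")) {
  stopifnot(inherits(calib, "calibration_result"))
  interval <- match.arg(interval)
  schedule <- resolve_schedule(schedule, calib$schedules)
  growth <- calib$growth_by_cell_line[[cell_line]]
  if (is.null(growth))
    stop_fd("unknown cell line ", cell_line, class = "fracdyn_config_error")

  sim_at <- function(par) {
    rad <- rad_from_params(calib$spec, setNames(par, names(calib$estimates)))
    simulate_confluence(calib$spec, growth, rad, schedule, N0,
                        calib$kinetics, output_times = times, dt = calib$dt,
                        gate_sharpness = calib$gate_sharpness)$N_total
  }
  est <- calib$estimates
  fit <- sim_at(est)

  G <- matrix(0, length(times), length(est))
  for (j in seq_along(est)) {
    h <- 1e-6 * max(abs(est[j]), 1e-4)
    up <- est; up[j] <- est[j] + h
    dn <- est; dn[j] <- max(est[j] - h, 0)
    G[, j] <- (sim_at(up) - sim_at(dn)) / (up[j] - dn[j])
  }
  v <- rowSums((G %*% calib$cov) * G)
  if (any(v < -1e-12)) warning("negative delta-method variance clipped at 0")
  v <- pmax(v, 0)
  if (interval == "prediction") v <- v + calib$sigma2
  tq <- stats::qt(1 - (1 - level) / 2, df = calib$m - calib$p)
  hw <- tq * sqrt(v)
  out <- data.frame(time = times, fit = fit, lwr = fit - hw, upr = fit + hw,
                    half_width = hw)
  class(out) <- c("fd_prediction", "data.frame")
  attr(out, "level") <- level
  attr(out, "interval") <- interval
  out
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between measurement and prediction; requires
#' at least 3 points and nonzero variance in both vectors.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_fd("need equal-length vectors with >= 3 points",
            class = "fracdyn_domain_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_fd("undefined Pearson correlation: zero variance",
            class = "fracdyn_metric_error")
  stats::cor(x, y)
}

#' Lin's concordance correlation coefficient
#'
#' `CCC = 2*s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (divide-by-n) moments. Measures agreement: unlike Pearson correlation it
#' penalizes scale and location shifts, so `|CCC| <= |PCC|`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return concordance in `[-1, 1]`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_fd("need equal-length vectors with >= 3 points",
            class = "fracdyn_domain_error")
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom == 0)
    stop_fd("undefined concordance: zero variances and equal means",
            class = "fracdyn_metric_error")
  2 * sxy / denom
}

#' Validate calibrated models on held-out curves
#'
#' For every validation replicate, predicts total confluence from only its
#' initial confluence and schedule (the same calibrated parameters are used
#' regardless of schedule or density), computes per-replicate Pearson and
#' concordance coefficients against the measurements, and aggregates
#' mean +/- standard error per (cell line, schedule), per total-dose group,
#' and overall. Replicates with undefined metrics (zero variance) are
#' reported and excluded from aggregation.
#'
#' @param calib_by_cell_line named list of [calibrate_global()] results,
#'   one per cell line.
#' @param validation_curves list of held-out [confluence_curve()]s.
#' @return object of class `validation_metrics`: `per_replicate`,
#'   `per_condition`, `per_total_dose`, `overall` data.frames.
#' @export
validate_predictions <- function(calib_by_cell_line, validation_curves) {
  rows <- lapply(sort_curves(validation_curves), function(cv) {
    calib <- calib_by_cell_line[[cv$cell_line]]
    if (is.null(calib))
      stop_fd("no calibration for cell line ", cv$cell_line,
              class = "fracdyn_data_error")
    sched <- resolve_schedule(cv$schedule_id, calib$schedules)
    pred <- predict_confluence(calib, cv$N0, sched, cv$times,
                               cell_line = cv$cell_line)
    pcc <- tryCatch(pearson_cc(cv$confluence, pred$fit),
                    fracdyn_metric_error = function(e) NA_real_)
    ccc <- tryCatch(lin_ccc(cv$confluence, pred$fit),
                    fracdyn_metric_error = function(e) NA_real_)
    data.frame(replicate_id = cv$replicate_id, cell_line = cv$cell_line,
               schedule_id = cv$schedule_id,
               total_dose = sched$total_dose,
               n_points = length(cv$times), pcc = pcc, ccc = ccc)
  })
  per_rep <- do.call(rbind, rows)
  rownames(per_rep) <- NULL

  agg <- function(df, by) {
    keys <- unique(df[by])
    out <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sel <- rep(TRUE, nrow(df))
      for (b in by) sel <- sel & df[[b]] == keys[[b]][i]
      sub <- df[sel & !is.na(df$pcc) & !is.na(df$ccc), , drop = FALSE]
      n <- nrow(sub)
      cbind(keys[i, , drop = FALSE],
            data.frame(n = n,
                       pcc_mean = mean(sub$pcc),
                       pcc_se = stats::sd(sub$pcc) / sqrt(n),
                       ccc_mean = mean(sub$ccc),
                       ccc_se = stats::sd(sub$ccc) / sqrt(n)))
    }))
    rownames(out) <- NULL
    out
  }
  per_rep$all <- "all"
  structure(list(per_replicate = per_rep[setdiff(names(per_rep), "all")],
                 per_condition = agg(per_rep, c("cell_line", "schedule_id")),
                 per_total_dose = agg(per_rep, c("cell_line", "total_dose")),
                 overall = agg(per_rep, c("cell_line", "all"))),
            class = "validation_metrics")
}

#' @export
print.validation_metrics <- function(x, ...) {
  cat("Prediction accuracy per condition (mean +/- SE over replicates):\n")
  print(x$per_condition, row.names = FALSE, digits = 3)
  cat("\nOverall:\n")
  print(x$overall, row.names = FALSE, digits = 3)
  invisible(x)
}
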