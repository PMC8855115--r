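# Calibration context: everything about a training set that does not depend
# on the parameter vector is resolved once (schedule objects, repair rates,
# output grid indices), so residual evaluations inside the optimizer stay
# cheap.
calibration_context <- function(spec, curves, growth_by_cell_line, kinetics,
                                schedules = schedule_presets(),
                                dt = 0.01, gate_sharpness = 1) {
  stopifnot(inherits(spec, "model_spec"))
  curves <- sort_curves(curves)
  prep <- lapply(curves, function(cv) {
    if (!cv$cell_line %in% names(growth_by_cell_line))
      stop_fd("no growth parameters for cell line ", cv$cell_line,
              class = "fracdyn_config_error")
    sched <- resolve_schedule(cv$schedule_id, schedules)
    if (spec$senescence &&
        !total_dose_label(sched$total_dose) %in%
          vapply(spec$k_ps_doses, total_dose_label, ""))
      stop_fd("spec has no k_ps dose entry for schedule ", sched$id,
              class = "fracdyn_config_error")
    horizon <- max(cv$times)
    n_steps <- as.integer(ceiling(horizon / dt - 1e-9))
    out_idx <- pmin(as.integer(floor(cv$times / dt + 1e-9)), n_steps)
    list(curve = cv, growth = growth_by_cell_line[[cv$cell_line]],
         schedule = sched,
         krep = repair_rate_at_dose(kinetics, sched$dose_per_fraction),
         n_steps = n_steps, out_idx = out_idx)
  })
  m_per <- vapply(prep, function(p) length(p$curve$times), 0L)
  off <- cumsum(c(0L, utils::head(m_per, -1L)))
  for (i in seq_along(prep)) prep[[i]]$row <- off[i] + seq_len(m_per[i])
  par_names <- spec$free_parameter_names
  kps_labels <- vapply(prep, function(p)
    total_dose_label(p$schedule$total_dose), "")
  frac_list <- lapply(prep, function(p) p$schedule$fraction_times)
  list(spec = spec, prep = prep, kinetics = kinetics, dt = dt,
       gate_sharpness = gate_sharpness,
       m = sum(m_per),
       par_names = par_names,
       par_idx = setNames(seq_along(par_names), par_names),
       n0 = vapply(prep, function(p) p$curve$N0, 0),
       dpf = vapply(prep, function(p) p$schedule$dose_per_fraction, 0),
       kps_idx = if (spec$senescence)
         match(paste0("k_ps_", kps_labels), par_names) else rep(NA_integer_,
                                                               length(prep)),
       # flattened arrays for the batch residual kernel
       kp = vapply(prep, function(p) p$growth$k_p, 0),
       theta = vapply(prep, function(p) p$growth$theta, 0),
       A = vapply(prep, function(p) p$growth$A, 0),
       krep = vapply(prep, function(p) p$krep, 0),
       n_steps = vapply(prep, function(p) p$n_steps, 0L),
       frac_times = unlist(frac_list, use.names = FALSE),
       frac_off = as.integer(cumsum(c(0L, lengths(frac_list)))),
       out_idx = unlist(lapply(prep, function(p) p$out_idx),
                        use.names = FALSE),
       out_off = as.integer(c(0L, cumsum(m_per))),
       data = unlist(lapply(prep, function(p) p$curve$confluence),
                     use.names = FALSE),
       replicate_ids = vapply(prep, function(p) p$curve$replicate_id, ""))
}

# per-curve death-rate coefficients for a free-parameter vector, vectorized
# over curves (hot path of the optimizer)
ctx_coefs <- function(ctx, par) {
  s <- ctx$spec
  ix <- ctx$par_idx
  nc <- length(ctx$n0)
  ka <- switch(s$early,
    full = (par[ix[["alpha_acute_N"]]] * ctx$n0 + 1) *
      par[ix[["k_acute_D"]]] * ctx$dpf,
    dose_only = par[ix[["k_acute_D"]]] * ctx$dpf,
    density_only = par[ix[["k_acute_N"]]] * ctx$n0,
    none = numeric(nc))
  kacc <- switch(s$late,
    full = (par[ix[["alpha_accum_N"]]] * ctx$n0 + 1) *
      par[ix[["k_accum_D"]]] * ctx$dpf,
    dose_only = par[ix[["k_accum_D"]]] * ctx$dpf,
    density_only = par[ix[["k_accum_N"]]] * ctx$n0,
    none = numeric(nc))
  list(ka = ka, kacc = kacc,
       r = if (s$late == "none") 0 else par[ix[["r"]]],
       kps_n0 = if (s$senescence) par[ctx$kps_idx] * ctx$n0 else numeric(nc))
}

#' Global residual vector for a parameter vector
#'
#' Simulates every training curve with its own initial confluence and
#' schedule under a shared free-parameter vector (the `k_ps` entry is chosen
#' by each curve's total dose) and returns model-minus-data differences
#' concatenated in canonical order (curves sorted by `replicate_id`, then
#' time).
#'
#' @param par named numeric vector over `spec$free_parameter_names`.
#' @param spec a [model_spec()].
#' @param curves list of [confluence_curve()]s (the training set).
#' @param growth_by_cell_line named list of [growth_params()] per cell line.
#' @param kinetics a [repair_kinetics()].
#' @param schedules named list of available [dose_schedule()]s.
#' @param dt Euler step (hr).
#' @param gate_sharpness tanh gate sharpness.
#' @return numeric residual vector (length = total observation count).
#' @export
residuals_global <- function(par, spec, curves, growth_by_cell_line, kinetics,
                             schedules = schedule_presets(), dt = 0.01,
                             gate_sharpness = 1) {
  ctx <- calibration_context(spec, curves, growth_by_cell_line, kinetics,
                             schedules, dt, gate_sharpness)
  miss <- setdiff(ctx$par_names, names(par))
  if (length(miss))
    stop_fd("missing parameters: ", paste(miss, collapse = ", "),
            class = "fracdyn_config_error")
  ctx_residuals(ctx, par[ctx$par_names])
}

ctx_residuals <- function(ctx, par) {
  cf <- ctx_coefs(ctx, as.numeric(par))
  tryCatch(
    euler_residuals_cpp(ctx$n0, ctx$kp, ctx$theta, ctx$A, cf$kps_n0,
                        cf$ka, ctx$krep, cf$kacc, cf$r,
                        ctx$gate_sharpness, ctx$dt, ctx$n_steps,
                        ctx$frac_times, ctx$frac_off,
                        ctx$out_idx, ctx$out_off, ctx$data),
    error = function(e)
      stop_fd("simulation failed (", conditionMessage(e), ") for one of: ",
              paste(ctx$replicate_ids, collapse = ", "),
              class = "fracdyn_residual_error"))
}

# central finite-difference Jacobian of the residual vector, relative step
# matching the delta-method gradient convention
ctx_jacobian <- function(ctx, par, rel_step = 1e-6) {
  p <- length(par)
  r0 <- ctx_residuals(ctx, par)
  J <- matrix(0, length(r0), p)
  for (j in seq_len(p)) {
    h <- rel_step * max(abs(par[j]), 1e-4)
    up <- par; up[j] <- par[j] + h
    dn <- par; dn[j] <- max(par[j] - h, 0)
    J[, j] <- (ctx_residuals(ctx, up) - ctx_residuals(ctx, dn)) /
      (up[j] - dn[j])
  }
  colnames(J) <- ctx$par_names
  J
}

default_init <- function(par_names) {
  cls <- param_class(par_names)
  setNames(ifelse(cls == "scale", 1, 3e-3), par_names)
}

draw_starts <- function(par_names, n_starts, seed, init = NULL) {
  cls <- param_class(par_names)
  starts <- list()
  if (!is.null(init)) starts[[1L]] <- setNames(as.numeric(init), par_names)
  need <- n_starts - length(starts)
  if (need > 0) {
    draws <- withr::with_seed(seed, {
      lapply(seq_len(need), function(i) {
        lo <- ifelse(cls == "scale", 1e-2, 1e-5)
        hi <- ifelse(cls == "scale", 1e2, 1e-1)
        setNames(exp(runif(length(par_names), log(lo), log(hi))), par_names)
      })
    })
    starts <- c(starts, draws)
  }
  starts
}

#' Global bounded least-squares calibration
#'
#' Fits a model's free parameters to all training curves simultaneously by
#' bounded Levenberg-Marquardt (lower bound zero on every parameter, from
#' the parameters' biological definitions), with seeded multi-start
#' initialization; the start reaching the lowest RSS wins. Confidence
#' intervals use the finite-difference Jacobian at the optimum:
#' `Cov = (J'J)^-1 * RSS/(m - p)` and t quantiles with `m - p` degrees of
#' freedom.
#'
#' @inheritParams residuals_global
#' @param init optional named start vector (used as the first start).
#' @param n_starts number of starts (default 8); additional starts are drawn
#'   log-uniformly, rates over `[1e-5, 1e-1]` and dimensionless scales over
#'   `[1e-2, 1e2]`.
#' @param seed integer seed for the start draws.
#' @param level confidence level for intervals (default 0.95).
#' @param control list passed to [lsq_bounded()] (`ftol`, `ptol`, `maxfev`,
#'   `max_iter`).
#' @param coarse_dt optional coarser Euler step for the multi-start stage
#'   (two-grid strategy: the global search runs on the cheap grid and only
#'   the winning start is polished at `dt`). `NULL` (default) fits every
#'   start at `dt`.
#' @return object of class `calibration_result`: `spec`, `estimates`,
#'   `residuals`, `rss`, `jacobian`, `cov`, `se`, `ci` (matrix with columns
#'   `lower`, `upper`), `correlation` (parameter correlation from the
#'   scale-free `(J'J)^-1` structure), `collinear_pairs` (|cor| > 0.99),
#'   `sensitivity` (RMS trajectory change per 100% parameter change; a
#'   parameter well below `sqrt(sigma2)` is practically unidentifiable at
#'   the data's noise level), `m`, `p`, `sigma2`, `converged`, `starts`
#'   (per-start RSS/convergence), `seed`, `dt`, `level`, plus the context
#'   pieces needed for prediction.
#' @export
calibrate_global <- function(spec, curves, growth_by_cell_line, kinetics,
                             schedules = schedule_presets(),
                             init = NULL, n_starts = 8, seed = 1,
                             dt = 0.01, gate_sharpness = 1, level = 0.95,
                             control = list(), coarse_dt = NULL) {
  ctx <- calibration_context(spec, curves, growth_by_cell_line, kinetics,
                             schedules, dt, gate_sharpness)
  p <- length(ctx$par_names)
  if (p == 0L)
    stop_fd("model has no free parameters", class = "fracdyn_config_error")
  if (p >= ctx$m)
    stop_fd("need more observations (", ctx$m, ") than parameters (", p, ")",
            class = "fracdyn_config_error")
  ctrl <- modifyList(list(ftol = 1e-10, ptol = 1e-10, maxfev = 2000,
                          max_iter = 200), control)
  starts <- draw_starts(ctx$par_names, n_starts, seed, init)
  # optimize in log space: parameters are positive rates/scales spanning
  # orders of magnitude, so log coordinates equalize conditioning and make
  # the zero lower bound a (practically reachable) open boundary at
  # exp(z_min) ~ 1e-12
  z_min <- log(1e-12)
  z_max <- log(1e6)
  ctx_search <- if (is.null(coarse_dt)) ctx else
    calibration_context(spec, curves, growth_by_cell_line, kinetics,
                        schedules, coarse_dt, gate_sharpness)
  fn_z <- function(z) ctx_residuals(ctx_search, exp(z))
  fits <- lapply(starts, function(st)
    lsq_bounded(fn_z, pmin(pmax(log(pmax(st, 1e-12)), z_min), z_max),
                lower = z_min, upper = z_max,
                ftol = ctrl$ftol, ptol = ctrl$ptol,
                maxfev = ctrl$maxfev, max_iter = ctrl$max_iter,
                typical = 1, step_max_factor = 3))
  rss_all <- vapply(fits, function(f) f$rss, 0)
  best <- fits[[which.min(rss_all)]]
  # final polish in raw coordinates on the target grid: log coordinates are
  # good for the global search but lose gradient for parameters near zero
  # (d/dz = x d/dx), so the last mile runs bounded LM on the raw scale
  typ <- ifelse(param_class(ctx$par_names) == "scale", 1, 1e-2)
  best <- lsq_bounded(function(x) ctx_residuals(ctx, x), exp(best$par),
                      lower = 0, upper = Inf,
                      ftol = ctrl$ftol, ptol = ctrl$ptol,
                      maxfev = ctrl$maxfev, max_iter = ctrl$max_iter,
                      typical = typ, step_max_factor = 4)
  est <- setNames(best$par, ctx$par_names)
  est[est <= 1.5e-12] <- 0  # boundary estimates are zeros, not 1e-12s

  J <- ctx_jacobian(ctx, est)
  sigma2 <- best$rss / (ctx$m - p)
  JtJ <- crossprod(J)
  cov_flag <- NULL
  covm <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
  if (is.null(covm) || any(!is.finite(covm))) {
    covm <- pinv(JtJ) * sigma2
    cov_flag <- "singular J'J: covariance from pseudo-inverse"
    warning(cov_flag)
  }
  dimnames(covm) <- list(ctx$par_names, ctx$par_names)
  se <- sqrt(pmax(diag(covm), 0))
  tq <- stats::qt(1 - (1 - level) / 2, df = ctx$m - p)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  # parameter correlation from the (J'J)^-1 structure alone, so the audit
  # stays meaningful for noise-free fits where sigma2 ~ 0
  str_cov <- tryCatch(solve(JtJ), error = function(e) pinv(JtJ))
  dnorm_ <- sqrt(pmax(diag(str_cov), .Machine$double.eps))
  corr <- str_cov / tcrossprod(dnorm_)
  dimnames(corr) <- list(ctx$par_names, ctx$par_names)
  # scaled sensitivity: RMS trajectory change for a 100% parameter change,
  # comparable against the residual noise floor sqrt(sigma2) -- parameters
  # far below that floor are practically unidentifiable at this noise level
  sensitivity <- sqrt(colMeans(J^2)) * abs(est)
  coll <- which(abs(corr) > 0.99 & upper.tri(corr), arr.ind = TRUE)
  collinear_pairs <- if (nrow(coll))
    data.frame(par_a = ctx$par_names[coll[, 1L]],
               par_b = ctx$par_names[coll[, 2L]],
               correlation = corr[coll]) else
    data.frame(par_a = character(), par_b = character(),
               correlation = numeric())

  structure(list(spec = spec, estimates = est, residuals = best$residuals,
                 rss = best$rss, jacobian = J, cov = covm, se = se, ci = ci,
                 correlation = corr, collinear_pairs = collinear_pairs,
                 sensitivity = sensitivity,
                 m = ctx$m, p = p, sigma2 = sigma2,
                 converged = best$converged, message = best$message,
                 cov_flag = cov_flag,
                 starts = data.frame(start = seq_along(fits),
                                     rss = rss_all,
                                     converged = vapply(fits, function(f)
                                       f$converged, TRUE)),
                 seed = seed, dt = dt, gate_sharpness = gate_sharpness,
                 level = level,
                 growth_by_cell_line = growth_by_cell_line,
                 kinetics = kinetics, schedules = schedules),
            class = "calibration_result")
}

# Moore-Penrose pseudo-inverse via SVD (fallback for singular J'J)
pinv <- function(X, tol = .Machine$double.eps^0.75) {
  s <- svd(X)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(X), nrow(X)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Compare a parameter between two calibrated cell lines
#'
#' Two-sided z-test on the difference of two independent estimates:
#' `z = (a - b) / sqrt(se_a^2 + se_b^2)`.
#'
#' @param result_a,result_b [calibrate_global()] results.
#' @param parameter free-parameter name present in both.
#' @param alpha significance level (default 0.05).
#' @return list with `z`, `p_value`, `significant`, `estimates`, `ses`.
#' @export
compare_cell_lines <- function(result_a, result_b, parameter, alpha = 0.05) {
  for (res in list(result_a, result_b))
    if (!parameter %in% names(res$estimates))
      stop_fd("parameter '", parameter, "' not free in both results",
              class = "fracdyn_domain_error")
  a <- result_a$estimates[[parameter]]; sa <- result_a$se[[parameter]]
  b <- result_b$estimates[[parameter]]; sb <- result_b$se[[parameter]]
  z <- (a - b) / sqrt(sa^2 + sb^2)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p_value = p, significant = p < alpha,
       estimates = c(a = a, b = b), ses = c(a = sa, b = sb))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration of model %s: %d observations, %d parameters, RSS = %.4g\n",
              ifelse(is.na(x$spec$id), "ad-hoc", x$spec$id), x$m, x$p, x$rss))
  tab <- data.frame(estimate = x$estimates, se = x$se,
                    ci_lower = x$ci[, "lower"], ci_upper = x$ci[, "upper"])
  print(tab)
  cat("converged:", x$converged, "-", x$message, "\n")
  invisible(x)
}
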