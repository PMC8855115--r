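#' Untreated growth parameters
#'
#' Logistic growth with an Allee factor:
#' `dN/dt = k_p * N * (N/theta + A) * (1 - N/theta)`.
#' `k_p` is the proliferation rate (1/hr), `theta` the carrying capacity on
#' the dimensionless confluence scale (0 < theta <= 1), and `A` the Allee
#' constant (>= 0; per-capita growth at low density scales with `A`).
#' These are measured on untreated control wells and held fixed during
#' radiation-response calibration.
#'
#' @param k_p proliferation rate, 1/hr, >= 0.
#' @param theta carrying capacity, confluence fraction in (0, 1].
#' @param A Allee constant, dimensionless, >= 0.
#' @return object of class `growth_params`.
#' @export
growth_params <- function(k_p, theta, A) {
  if (!is.finite(k_p) || k_p < 0)
    stop_fd("k_p must be >= 0", class = "fracdyn_config_error")
  if (!is.finite(theta) || theta <= 0 || theta > 1)
    stop_fd("theta must lie in (0, 1]", class = "fracdyn_config_error")
  if (!is.finite(A) || A < 0)
    stop_fd("A must be >= 0", class = "fracdyn_config_error")
  structure(list(k_p = k_p, theta = theta, A = A), class = "growth_params")
}

#' Untreated growth rate (right-hand side)
#'
#' @param N confluence (>= 0); may be a vector.
#' @param growth a [growth_params()] object.
#' @return dN/dt in confluence/hr.
#' @export
untreated_rhs <- function(N, growth) {
  stopifnot(inherits(growth, "growth_params"))
  if (any(N < 0)) stop_fd("N must be >= 0", class = "fracdyn_domain_error")
  growth$k_p * N * (N / growth$theta + growth$A) * (1 - N / growth$theta)
}

#' Synthetic untreated-growth presets
#'
#' Stand-in control-well growth parameters per cell line (the measured
#' values come from a prior untreated-control fit and are not public).
#' Doubling time at low density is about `log(2)/(k_p*A)`.
#'
#' @param cell_line `"9L"` or `"C6"`.
#' @return a [growth_params()] object.
#' @export
synthetic_growth_params <- function(cell_line = c("9L", "C6")) {
  cell_line <- match.arg(cell_line)
  if (cell_line == "9L") growth_params(k_p = 0.035, theta = 0.95, A = 1)
  else                   growth_params(k_p = 0.032, theta = 0.90, A = 1)
}

#' Fit untreated growth parameters to a control curve
#'
#' Convenience least-squares fit of `(k_p, theta, A)` to an untreated
#' confluence time series, integrating the growth law with the same explicit
#' Euler scheme used for treated simulations. Intended for synthetic control
#' wells; bounds keep `theta <= 1` and everything nonnegative.
#'
#' @param times,confluence observed control curve (times in hr, strictly
#'   increasing from 0).
#' @param init optional named start values `c(k_p=, theta=, A=)`.
#' @param dt Euler step (hr).
#' @return list with `growth` (a [growth_params()]), `rss`, `converged`.
#' @export
fit_growth_params <- function(times, confluence, init = NULL, dt = 0.01) {
  stopifnot(length(times) == length(confluence), length(times) >= 4L)
  n0 <- confluence[1L]
  if (is.null(init))
    init <- c(k_p = 0.03, theta = min(1, max(confluence) * 1.05 + 1e-3), A = 1)
  resid_fn <- function(p) {
    g <- growth_params(p[1L], min(max(p[2L], 1e-6), 1), p[3L])
    sim <- simulate_untreated(g, n0, output_times = times, dt = dt)
    sim$N_total - confluence
  }
  fit <- lsq_bounded(resid_fn, unname(init),
                     lower = c(1e-6, 1e-3, 0), upper = c(1, 1, 100))
  list(growth = growth_params(fit$par[1L], fit$par[2L], fit$par[3L]),
       rss = fit$rss, converged = fit$converged)
}

#' Simulate untreated growth
#'
#' Explicit Euler integration of the growth law alone (no radiation terms).
#'
#' @param growth a [growth_params()] object.
#' @param N0 initial confluence (> 0).
#' @param output_times times at which to report the state (hr).
#' @param dt Euler step (hr).
#' @return data.frame with `time`, `N_p`, `N_s` (all zero), `N_total`.
#' @export
simulate_untreated <- function(growth, N0, output_times, dt = 0.01) {
  spec <- model_spec(early = "none", late = "none",
                     senescence = FALSE, k_ps_doses = numeric())
  rad <- radiation_params()
  sched <- dose_schedule(0, 1)  # dose irrelevant: all radiation terms off
  kin <- repair_kinetics(c(1, 2), c(0.1, 0.1))
  simulate_confluence(spec, growth, rad, sched, N0, kin,
                      output_times = output_times, dt = dt)
}
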