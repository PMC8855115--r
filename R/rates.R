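# Per-fraction death-rate coefficients. Both early and late coefficients are
# "average across fractions" quantities: the same coefficient applies to
# every fraction of a schedule (doses per fraction are equal within a
# schedule).

acute_coefficient <- function(spec, rad, schedule, N0) {
  D <- schedule$dose_per_fraction
  switch(spec$early,
    full = (rad$alpha_acute_N * N0 + 1) * rad$k_acute_D * D,
    dose_only = rad$k_acute_D * D,
    density_only = rad$k_acute_N * N0,
    none = 0)
}

accum_coefficient <- function(spec, rad, schedule, N0) {
  D <- schedule$dose_per_fraction
  switch(spec$late,
    full = (rad$alpha_accum_N * N0 + 1) * rad$k_accum_D * D,
    dose_only = rad$k_accum_D * D,
    density_only = rad$k_accum_N * N0,
    none = 0)
}

kps_rate <- function(spec, rad, schedule) {
  if (!spec$senescence) return(0)
  lab <- total_dose_label(schedule$total_dose)
  if (!lab %in% names(rad$k_ps))
    stop_fd("no k_ps entry for total dose ", lab, " Gy",
            class = "fracdyn_config_error")
  unname(rad$k_ps[[lab]])
}

#' Early (acute) death rate
#'
#' Sum over delivered fractions of the acute coefficient times the fraction
#' of DSBs still unrepaired, smoothed by a tanh gate:
#' `k_ed(t) = sum_i coef * f_DSB(t_i, D) * tanh(s * f_DSB(t_i, D))`,
#' where `t_i` is the time since fraction i (terms for undelivered fractions
#' are zero). The gate keeps the trajectory continuous at fraction times;
#' its sharpness `s` rescales magnitude, which the calibrated coefficient
#' absorbs.
#'
#' @param t time(s) in hr.
#' @param spec a [model_spec()].
#' @param rad a [radiation_params()].
#' @param schedule a [dose_schedule()].
#' @param N0 initial confluence of the replicate.
#' @param kinetics a [repair_kinetics()].
#' @param gate_sharpness tanh gate sharpness `s` (default 1, literal gate).
#' @return early death rate(s), 1/hr.
#' @export
early_death_rate <- function(t, spec, rad, schedule, N0, kinetics,
                             gate_sharpness = 1) {
  coef <- acute_coefficient(spec, rad, schedule, N0)
  if (coef == 0) return(rep(0, length(t)))
  krep <- repair_rate_at_dose(kinetics, schedule$dose_per_fraction)
  out <- numeric(length(t))
  for (ft in schedule$fraction_times) {
    active <- t > ft
    ti <- pmax(t - ft, 0)
    f <- exp(-krep * ti)
    out <- out + ifelse(active, coef * f * tanh(gate_sharpness * f), 0)
  }
  out
}

#' Late (accumulation) death rate
#'
#' Sum over delivered fractions of the accumulation coefficient times
#' `t_i * exp(-r * t_i)`: misrepair accumulates, then the radiation efficacy
#' decays at rate `r`. For a single fraction the rate starts at 0, peaks at
#' `t = 1/r`, and decays.
#'
#' @inheritParams early_death_rate
#' @return late death rate(s), 1/hr.
#' @export
late_death_rate <- function(t, spec, rad, schedule, N0) {
  coef <- accum_coefficient(spec, rad, schedule, N0)
  if (coef == 0) return(rep(0, length(t)))
  out <- numeric(length(t))
  for (ft in schedule$fraction_times) {
    ti <- pmax(t - ft, 0)
    out <- out + coef * ti * exp(-rad$r * ti)
  }
  out
}

#' Two-compartment treated right-hand side
#'
#' `dN_p/dt = (k_p - k_ld(t)) * ((N_p+N_s)/theta + A) * N_p *
#'            (1 - (N_p+N_s)/theta) - k_ed(t) * N_p - k_ps * N0 * N_p`
#' `dN_s/dt = k_ps * N0 * N_p`
#'
#' Only proliferative cells divide (the growth product multiplies `N_p`),
#' while crowding acts through the shared total `N_p + N_s`. With the
#' senescent compartment inactive the `k_ps` terms vanish and the system
#' reduces to the single-species treated model; with all radiation
#' parameters zero it reduces to [untreated_rhs()].
#'
#' @param state numeric `c(N_p, N_s)`.
#' @param t time in hr.
#' @param growth a [growth_params()].
#' @inheritParams early_death_rate
#' @return numeric `c(dN_p/dt, dN_s/dt)`.
#' @export
treated_rhs <- function(state, t, spec, growth, rad, schedule, N0, kinetics,
                        gate_sharpness = 1) {
  np <- state[[1L]]; ns <- state[[2L]]
  if (np < 0 || ns < 0)
    stop_fd("state must be nonnegative", class = "fracdyn_domain_error")
  ked <- early_death_rate(t, spec, rad, schedule, N0, kinetics, gate_sharpness)
  kld <- late_death_rate(t, spec, rad, schedule, N0)
  kps <- kps_rate(spec, rad, schedule)
  ntot <- np + ns
  grow <- (growth$k_p - kld) * (ntot / growth$theta + growth$A) * np *
    (1 - ntot / growth$theta)
  dnp <- grow - ked * np - kps * N0 * np
  dns <- kps * N0 * np
  c(dnp, dns)
}
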