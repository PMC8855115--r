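#' Candidate model specification
#'
#' Identifies one member of the radiation-response model family by the
#' functional form of its early (acute) death coefficient, its late
#' (accumulation) death coefficient, and whether the senescent compartment
#' is active. The per-fraction death-rate coefficients are:
#'
#' * early `"full"`: `(alpha_acute_N*N0 + 1) * k_acute_D * D`
#' * early `"dose_only"`: `k_acute_D * D`
#' * early `"density_only"`: `k_acute_N * N0`
#' * early `"none"`: 0
#'
#' and analogously for the late form with `alpha_accum_N`, `k_accum_D`,
#' `k_accum_N`. The radiation-efficacy decay rate `r` is free whenever the
#' late form is active; the senescence conversion rate `k_ps` is one free
#' parameter per distinct total dose in `k_ps_doses`.
#'
#' @param id model id 1-8 (or `NA` for ad-hoc specs outside the family).
#' @param early,late one of `"full"`, `"dose_only"`, `"density_only"`,
#'   `"none"`.
#' @param senescence logical; is the senescent compartment active?
#' @param k_ps_doses total doses (Gy) for which a `k_ps` parameter exists
#'   (ignored when `senescence = FALSE`).
#' @return object of class `model_spec` with the ordered
#'   `free_parameter_names`.
#' @export
model_spec <- function(id = NA_integer_, early, late, senescence,
                       k_ps_doses = c(16, 20)) {
  forms <- c("full", "dose_only", "density_only", "none")
  early <- match.arg(early, forms)
  late <- match.arg(late, forms)
  stopifnot(is.logical(senescence), length(senescence) == 1L)
  early_par <- switch(early,
    full = c("alpha_acute_N", "k_acute_D"),
    dose_only = "k_acute_D",
    density_only = "k_acute_N",
    none = character())
  late_par <- switch(late,
    full = c("alpha_accum_N", "k_accum_D"),
    dose_only = "k_accum_D",
    density_only = "k_accum_N",
    none = character())
  if (late != "none") late_par <- c(late_par, "r")
  kps_par <- if (senescence && length(k_ps_doses))
    paste0("k_ps_", vapply(sort(k_ps_doses), total_dose_label, "")) else character()
  structure(list(id = as.integer(id), early = early, late = late,
                 senescence = senescence,
                 k_ps_doses = if (senescence) sort(k_ps_doses) else numeric(),
                 free_parameter_names = c(early_par, late_par, kps_par)),
            class = "model_spec")
}

#' The eight-member candidate family
#'
#' Model 1 is the full model; models 2-4 reduce the early-death coefficient
#' (dose-only, density-only, none), models 5-7 reduce the late-death
#' coefficient (dose-only, density-only, none -- dropping `r` as well), and
#' model 8 removes the senescent compartment. Model 3 (density-only early
#' death, full late death, senescence on) is the member selected as most
#' parsimonious for both glioma lines; with two total doses it has six free
#' parameters.
#'
#' @param k_ps_doses total doses (Gy) needing a `k_ps` parameter.
#' @return list of 8 [model_spec()] objects, names `"model_1"` ... `"model_8"`.
#' @export
model_family <- function(k_ps_doses = c(16, 20)) {
  specs <- list(
    model_spec(1L, "full",         "full",         TRUE,  k_ps_doses),
    model_spec(2L, "dose_only",    "full",         TRUE,  k_ps_doses),
    model_spec(3L, "density_only", "full",         TRUE,  k_ps_doses),
    model_spec(4L, "none",         "full",         TRUE,  k_ps_doses),
    model_spec(5L, "full",         "dose_only",    TRUE,  k_ps_doses),
    model_spec(6L, "full",         "density_only", TRUE,  k_ps_doses),
    model_spec(7L, "full",         "none",         TRUE,  k_ps_doses),
    model_spec(8L, "full",         "full",         FALSE, k_ps_doses))
  names(specs) <- paste0("model_", 1:8)
  specs
}

#' Radiation-response parameters
#'
#' Container for the radiation parameters; only the entries a given
#' [model_spec()] marks as active are used. Units follow dimensional
#' consistency of the governing rate equations: `k_acute_D` in 1/(hr Gy),
#' `k_acute_N` and `k_accum_N` in 1/hr, `k_accum_D` in 1/(hr^2 Gy)
#' (it multiplies elapsed time and dose), `r` in 1/hr, `alpha_*` and
#' `k_ps` entries as listed. `k_ps` is a named vector keyed by total dose
#' label (e.g. `c("16" = 0.05, "20" = 0.08)`), each in 1/hr.
#'
#' @param alpha_acute_N,k_acute_D,k_acute_N early-death coefficients.
#' @param alpha_accum_N,k_accum_D,k_accum_N late-death coefficients.
#' @param r radiation-efficacy decay rate (1/hr).
#' @param k_ps named numeric vector of senescence conversion rates by total
#'   dose label.
#' @return object of class `radiation_params`.
#' @export
radiation_params <- function(alpha_acute_N = 0, k_acute_D = 0, k_acute_N = 0,
                             alpha_accum_N = 0, k_accum_D = 0, k_accum_N = 0,
                             r = 0, k_ps = numeric()) {
  vals <- c(alpha_acute_N = alpha_acute_N, k_acute_D = k_acute_D,
            k_acute_N = k_acute_N, alpha_accum_N = alpha_accum_N,
            k_accum_D = k_accum_D, k_accum_N = k_accum_N, r = r)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_fd("radiation parameters must be finite and >= 0",
            class = "fracdyn_config_error")
  if (length(k_ps) && (any(!is.finite(k_ps)) || any(k_ps < 0)))
    stop_fd("k_ps entries must be finite and >= 0", class = "fracdyn_config_error")
  structure(c(as.list(vals), list(k_ps = k_ps)), class = "radiation_params")
}

#' Build radiation parameters from a free-parameter vector
#'
#' Maps a named vector over a spec's `free_parameter_names` onto a full
#' [radiation_params()] object (inactive entries zero).
#'
#' @param spec a [model_spec()].
#' @param par named numeric vector covering `spec$free_parameter_names`.
#' @return a [radiation_params()] object.
#' @export
rad_from_params <- function(spec, par) {
  stopifnot(inherits(spec, "model_spec"))
  miss <- setdiff(spec$free_parameter_names, names(par))
  if (length(miss))
    stop_fd("missing parameters: ", paste(miss, collapse = ", "),
            class = "fracdyn_config_error")
  g <- function(nm) if (nm %in% spec$free_parameter_names) unname(par[[nm]]) else 0
  kps_names <- grep("^k_ps_", spec$free_parameter_names, value = TRUE)
  k_ps <- setNames(vapply(kps_names, function(nm) unname(par[[nm]]), 0),
                   sub("^k_ps_", "", kps_names))
  radiation_params(alpha_acute_N = g("alpha_acute_N"),
                   k_acute_D = g("k_acute_D"), k_acute_N = g("k_acute_N"),
                   alpha_accum_N = g("alpha_accum_N"),
                   k_accum_D = g("k_accum_D"), k_accum_N = g("k_accum_N"),
                   r = g("r"), k_ps = k_ps)
}

# parameter class, used for log-uniform multistart draws
param_class <- function(names) {
  ifelse(grepl("^alpha_", names), "scale", "rate")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Model %s: early = %s, late = %s, senescence = %s\n",
              ifelse(is.na(x$id), "ad-hoc", x$id), x$early, x$late,
              x$senescence))
  cat("  free parameters:", paste(x$free_parameter_names, collapse = ", "),
      "\n")
  invisible(x)
}
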