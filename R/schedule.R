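#' Fractionation schedule
#'
#' Ordered fraction delivery times and the (equal) dose per fraction. The
#' nominal total dose may be specified separately to accommodate rounded
#' doses per fraction (e.g. 3 x 5.3 Gy nominally totals 16 Gy); it must agree
#' with `dose_per_fraction * n_fractions` within 2%.
#'
#' @param fraction_times nondecreasing delivery times in hr, first at 0.
#' @param dose_per_fraction dose per fraction in Gy (> 0).
#' @param total_dose nominal total dose in Gy; defaults to
#'   `dose_per_fraction * length(fraction_times)`.
#' @param id optional schedule label.
#' @return An object of class `dose_schedule` with fields `fraction_times`,
#'   `dose_per_fraction`, `total_dose`, `n_fractions`, `id`.
#' @examples
#' dose_schedule(c(0, 24), 8)          # 2 x 8 Gy
#' schedule_preset("16x3")             # 3 x 5.3 Gy, nominal 16 Gy
#' @export
dose_schedule <- function(fraction_times, dose_per_fraction,
                          total_dose = dose_per_fraction * length(fraction_times),
                          id = NULL) {
  fraction_times <- as.numeric(fraction_times)
  if (length(fraction_times) < 1L || is.unsorted(fraction_times) ||
      fraction_times[1L] != 0)
    stop_fd("fraction_times must be nondecreasing with first fraction at 0",
            class = "fracdyn_config_error")
  if (!is.finite(dose_per_fraction) || dose_per_fraction <= 0)
    stop_fd("dose_per_fraction must be positive", class = "fracdyn_config_error")
  nf <- length(fraction_times)
  if (abs(total_dose - dose_per_fraction * nf) > 0.02 * total_dose)
    stop_fd("total_dose inconsistent with dose_per_fraction * n_fractions ",
            "(beyond 2% rounding slack)", class = "fracdyn_config_error")
  structure(list(fraction_times = fraction_times,
                 dose_per_fraction = dose_per_fraction,
                 total_dose = total_dose,
                 n_fractions = nf,
                 id = id %||% sprintf("%gx%d", total_dose, nf)),
            class = "dose_schedule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Built-in fractionation presets
#'
#' The six experimental schedules: total dose 16 Gy delivered as 2 x 8,
#' 3 x 5.3 or 4 x 4 Gy, and total dose 20 Gy delivered as 2 x 10, 3 x 6.7 or
#' 4 x 5 Gy, all at 24-hour intervals starting at t = 0. Preset ids are
#' `"<total>x<n_fractions>"`, e.g. `"16x3"`.
#'
#' @return Named list of [dose_schedule()] objects.
#' @export
schedule_presets <- function() {
  mk <- function(total, dpf, nf)
    dose_schedule(24 * (seq_len(nf) - 1), dpf, total_dose = total,
                  id = sprintf("%dx%d", total, nf))
  list(`16x2` = mk(16, 8, 2),
       `16x3` = mk(16, 5.3, 3),
       `16x4` = mk(16, 4, 4),
       `20x2` = mk(20, 10, 2),
       `20x3` = mk(20, 6.7, 3),
       `20x4` = mk(20, 5, 4))
}

#' @param id preset id, one of `"16x2"`, `"16x3"`, `"16x4"`, `"20x2"`,
#'   `"20x3"`, `"20x4"`.
#' @rdname schedule_presets
#' @export
schedule_preset <- function(id) {
  ps <- schedule_presets()
  if (!id %in% names(ps))
    stop_fd("unknown schedule id '", id, "'; valid ids: ",
            paste(names(ps), collapse = ", "), class = "fracdyn_usage_error")
  ps[[id]]
}

resolve_schedule <- function(schedule, schedules = schedule_presets()) {
  if (inherits(schedule, "dose_schedule")) return(schedule)
  if (is.character(schedule) && length(schedule) == 1L) {
    if (schedule %in% names(schedules)) return(schedules[[schedule]])
    return(schedule_preset(schedule))
  }
  stop_fd("schedule must be a dose_schedule or a known schedule id",
          class = "fracdyn_usage_error")
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat(sprintf("Schedule %s: %d x %g Gy (total %g Gy) at t = %s hr\n",
              x$id, x$n_fractions, x$dose_per_fraction, x$total_dose,
              paste(x$fraction_times, collapse = ", ")))
  invisible(x)
}

# label used to key k_ps by total dose, e.g. 16 -> "16"
total_dose_label <- function(total_dose) sprintf("%g", total_dose)
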