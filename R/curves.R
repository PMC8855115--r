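#' A measured confluence curve
#'
#' One replicate well's time series of live-cell confluence. `N0` is the
#' confluence at time 0 (the first measurement) and serves as the model's
#' initial condition and density covariate.
#'
#' @param replicate_id unique replicate label.
#' @param cell_line cell-line label (e.g. `"9L"`).
#' @param schedule_id fractionation schedule id (e.g. `"16x4"`).
#' @param times measurement times in hr, strictly increasing, starting at 0.
#' @param confluence nonnegative confluence measurements, same length.
#' @return object of class `confluence_curve`.
#' @export
confluence_curve <- function(replicate_id, cell_line, schedule_id,
                             times, confluence) {
  times <- as.numeric(times)
  confluence <- as.numeric(confluence)
  if (length(times) != length(confluence) || length(times) < 1L)
    stop_fd("times and confluence must have equal positive length",
            class = "fracdyn_data_error")
  if (times[1L] != 0 || any(diff(times) <= 0))
    stop_fd("times must be strictly increasing and start at 0 (replicate ",
            replicate_id, ")", class = "fracdyn_data_error")
  if (any(confluence < 0) || any(!is.finite(confluence)))
    stop_fd("confluence must be finite and >= 0 (replicate ", replicate_id,
            ")", class = "fracdyn_data_error")
  structure(list(replicate_id = as.character(replicate_id),
                 cell_line = as.character(cell_line),
                 schedule_id = as.character(schedule_id),
                 times = times, confluence = confluence,
                 N0 = confluence[1L]),
            class = "confluence_curve")
}

#' Convert curves to/from a long data frame
#'
#' The tabular layout is `replicate_id, cell_line, schedule_id, time_hr,
#' confluence`.
#'
#' @param curves list of [confluence_curve()] objects.
#' @return `curves_to_df()`: a data.frame; `df_to_curves()`: a named list of
#'   curves sorted by `replicate_id`.
#' @export
curves_to_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cv)
    data.frame(replicate_id = cv$replicate_id, cell_line = cv$cell_line,
               schedule_id = cv$schedule_id, time_hr = cv$times,
               confluence = cv$confluence)))
}

#' @param df a data.frame in the long layout above.
#' @rdname curves_to_df
#' @export
df_to_curves <- function(df) {
  need <- c("replicate_id", "cell_line", "schedule_id", "time_hr", "confluence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_fd("missing column(s): ", paste(miss, collapse = ", "),
            class = "fracdyn_format_error")
  if (nrow(df) == 0L) return(list())
  key <- paste(df$replicate_id, df$time_hr)
  if (anyDuplicated(key)) {
    line <- which(duplicated(key))[1L]
    stop_fd("duplicated (replicate_id, time_hr) at data row ", line,
            " (replicate ", df$replicate_id[line], ", t = ",
            df$time_hr[line], ")", class = "fracdyn_data_error")
  }
  ids <- sort(unique(df$replicate_id))
  out <- lapply(ids, function(id) {
    sub <- df[df$replicate_id == id, , drop = FALSE]
    sub <- sub[order(sub$time_hr), , drop = FALSE]
    confluence_curve(id, sub$cell_line[1L], sub$schedule_id[1L],
                     sub$time_hr, sub$confluence)
  })
  names(out) <- ids
  out
}

#' Read / write curves CSV
#'
#' CSV with header `replicate_id,cell_line,schedule_id,time_hr,confluence`.
#' Reading groups rows by replicate, sorts times, and validates the layout;
#' writing is the exact inverse (round-trip identity).
#'
#' @param path file path.
#' @return `read_curves()` returns a named list of [confluence_curve()]s
#'   sorted by replicate id.
#' @export
read_curves <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("replicate_id", "cell_line", "schedule_id"))
    if (col %in% names(df)) df[[col]] <- as.character(df[[col]])
  df_to_curves(df)
}

#' @param curves list of [confluence_curve()]s.
#' @rdname read_curves
#' @export
write_curves <- function(curves, path) {
  df <- curves_to_df(curves)
  if (is.null(df))
    df <- data.frame(replicate_id = character(), cell_line = character(),
                     schedule_id = character(), time_hr = numeric(),
                     confluence = numeric())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# canonical ordering used everywhere residuals are concatenated
sort_curves <- function(curves) {
  ids <- vapply(curves, function(cv) cv$replicate_id, "")
  curves[order(ids)]
}
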