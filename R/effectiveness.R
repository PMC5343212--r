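MEASURES <- c("par", "accelerometer")

# Calendar convention used throughout: 6 months = 26 weeks, 12 months = 52
# weeks, so months = weeks * 6 / 26.
weeks_to_months <- function(weeks) weeks * 6 / 26

#' Repeated-measure MVPA trajectory for one arm and measure
#'
#' Holds mean weekly MVPA minutes (with SD and n) at each assessment week for
#' one trial arm and one measurement instrument. Week 0 is baseline; weeks
#' must be strictly increasing and the series must start at baseline.
#'
#' @param arm `"intervention"` or `"control"`.
#' @param measure `"par"` (7-day physical activity recall interview) or
#'   `"accelerometer"`.
#' @param week Integer-valued study weeks, starting at 0.
#' @param mean_weekly_minutes Mean weekly MVPA minutes at each week (>= 0).
#' @param sd,n Optional standard deviations and sample sizes per timepoint.
#' @return Object of class `outcome_series`: a data.frame of timepoints with
#'   attributes `arm` and `measure`.
#' @examples
#' s <- outcome_series("intervention", "par", c(0, 26, 52),
#'                     c(8.0, 112.8, 108.6))
#' cumulative_gain(s, 0, 26)
#' @export
outcome_series <- function(arm, measure, week, mean_weekly_minutes,
                           sd = NA_real_, n = NA_integer_) {
  arm <- match.arg(arm, ARMS)
  measure <- match.arg(measure, MEASURES)
  if (length(week) != length(mean_weekly_minutes)) {
    stop("`week` and `mean_weekly_minutes` must have equal length", call. = FALSE)
  }
  if (length(week) < 1) stop("series needs at least one timepoint", call. = FALSE)
  if (any(!is.finite(week)) || any(week < 0)) {
    stop("weeks must be nonnegative numbers", call. = FALSE)
  }
  if (is.unsorted(week, strictly = TRUE)) {
    stop("weeks must be strictly increasing", call. = FALSE)
  }
  if (week[1] != 0) {
    stop("series must start at the baseline timepoint (week 0)", call. = FALSE)
  }
  if (any(!is.finite(mean_weekly_minutes)) || any(mean_weekly_minutes < 0)) {
    stop("mean weekly minutes must be nonnegative", call. = FALSE)
  }
  tp <- data.frame(week = week, mean_weekly_minutes = mean_weekly_minutes,
                   sd = rep_len(sd, length(week)), n = rep_len(n, length(week)))
  structure(tp, arm = arm, measure = measure,
            class = c("outcome_series", "data.frame"))
}

#' @export
print.outcome_series <- function(x, ...) {
  cat("MVPA outcome series:", attr(x, "arm"), "arm,",
      attr(x, "measure"), "measure\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Interpolate mean weekly MVPA minutes at an arbitrary study week
#'
#' Piecewise-linear interpolation between assessment timepoints; exact at the
#' timepoints themselves. Extrapolation outside the observed window is
#' refused.
#'
#' @param series An [outcome_series()].
#' @param week Study week(s) within the series range.
#' @return Interpolated weekly minutes (same length as `week`).
#' @export
interpolate_weekly_minutes <- function(series, week) {
  stopifnot(inherits(series, "outcome_series"))
  if (any(week < min(series$week) - 1e-9 | week > max(series$week) + 1e-9)) {
    stop("week outside the observed range [", min(series$week), ", ",
         max(series$week), "]: no extrapolation", call. = FALSE)
  }
  if (nrow(series) == 1) {
    return(rep(series$mean_weekly_minutes, length(week)))
  }
  approx(series$week, series$mean_weekly_minutes, xout = week,
         method = "linear", ties = "ordered")$y
}

#' Cumulative per-person MVPA gain over a window
#'
#' Integrates the piecewise-linear interpolant of weekly MVPA minutes over
#' study weeks, after subtracting the baseline (week-0) weekly minutes:
#' the trapezoidal area between the trajectory and the flat baseline line.
#' For a single linear segment from baseline this reduces to
#' `(change in mean) / 2 * weeks`.
#'
#' @param series An [outcome_series()] (must include the week-0 baseline).
#' @param start_week,end_week Window bounds in study weeks,
#'   `start_week < end_week`, both within the series range.
#' @return Total minutes gained per person over the window (negative if
#'   activity fell below baseline).
#' @examples
#' s <- outcome_series("intervention", "par", c(0, 26), c(8.0, 112.8))
#' cumulative_gain(s, 0, 26) # 1362.4
#' @export
cumulative_gain <- function(series, start_week = 0,
                            end_week = max(series$week)) {
  stopifnot(inherits(series, "outcome_series"))
  if (series$week[1] != 0) {
    stop("series has no baseline (week 0) timepoint", call. = FALSE)
  }
  if (start_week >= end_week) {
    stop("`start_week` must be < `end_week`", call. = FALSE)
  }
  knots <- sort(unique(c(start_week, end_week,
                         series$week[series$week > start_week &
                                     series$week < end_week])))
  vals <- interpolate_weekly_minutes(series, knots) -
    series$mean_weekly_minutes[1]
  sum(diff(knots) * (vals[-length(vals)] + vals[-1]) / 2)
}

#' Convert a window gain to minutes per person per month
#'
#' @param total_minutes_gained Cumulative minutes gained over the window.
#' @param window_weeks Window length in weeks (> 0); 26 weeks = 6 months.
#' @return Minutes per person per month.
#' @examples
#' gain_per_month(1362.4, 26) # ~227
#' @export
gain_per_month <- function(total_minutes_gained, window_weeks) {
  stopifnot_scalar_num(total_minutes_gained, "total_minutes_gained")
  stopifnot_scalar_num(window_weeks, "window_weeks")
  if (window_weeks <= 0) stop("`window_weeks` must be > 0", call. = FALSE)
  total_minutes_gained / weeks_to_months(window_weeks)
}

#' Read outcome series from CSV
#'
#' @param path CSV with columns `arm`, `measure`, `week`,
#'   `mean_weekly_minutes` and optionally `sd`, `n`.
#' @return Named list of [outcome_series()], keyed `"<arm>.<measure>"`.
#' @export
read_outcome_series <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("arm", "measure", "week", "mean_weekly_minutes")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("outcomes file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sd" %in% names(raw)) raw$sd <- NA_real_
  if (!"n" %in% names(raw)) raw$n <- NA_integer_
  keys <- unique(paste(raw$arm, raw$measure, sep = "."))
  out <- lapply(keys, function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    sub <- raw[raw$arm == parts[1] & raw$measure == parts[2], ]
    sub <- sub[order(sub$week), ]
    outcome_series(parts[1], parts[2], sub$week, sub$mean_weekly_minutes,
                   sub$sd, sub$n)
  })
  setNames(out, keys)
}

#' Write outcome series to CSV
#'
#' @param series_list Named list of [outcome_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_outcome_series <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(arm = attr(s, "arm"), measure = attr(s, "measure"),
               week = s$week, mean_weekly_minutes = s$mean_weekly_minutes,
               sd = s$sd, n = s$n)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

series_key <- function(series_list, arm, measure) {
  key <- paste(arm, measure, sep = ".")
  if (!key %in% names(series_list)) {
    stop("missing outcome series for ", arm, " arm, ", measure,
         " measure", call. = FALSE)
  }
  series_list[[key]]
}
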