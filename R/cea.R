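#' Cost per minute of MVPA gained
#'
#' Per-arm cost-effectiveness ratio: cost per person divided by the average
#' per-person increase in MVPA minutes over the same window.
#'
#' @param per_person_cost Cost per person over the window, USD.
#' @param minutes_gained Average per-person minutes gained (nonzero).
#' @param rounded Round the ratio to cents (the reporting convention)?
#'   Set `FALSE` to obtain the raw ratio.
#' @return USD per minute.
#' @examples
#' cost_per_minute(10712 / 104, 1362.4) # 0.08
#' @export
cost_per_minute <- function(per_person_cost, minutes_gained, rounded = TRUE) {
  stopifnot_scalar_num(per_person_cost, "per_person_cost")
  stopifnot_scalar_num(minutes_gained, "minutes_gained")
  if (minutes_gained == 0) {
    stop("undefined ratio: minutes gained is zero", call. = FALSE)
  }
  r <- per_person_cost / minutes_gained
  if (rounded) round_cents(r) else r
}

#' Incremental cost per minute of MVPA gained (ICER)
#'
#' The additional cost per additional minute gained in the intervention arm
#' beyond the control arm: difference in per-person cost divided by the
#' difference in per-person minute gains. A negative value signals dominance
#' (one arm is both cheaper and more effective) and is returned with sign
#' preserved.
#'
#' @param cost_i,cost_c Per-person cost in the intervention and control arm,
#'   USD.
#' @param gain_i,gain_c Per-person minutes gained in each arm (must differ).
#' @param rounded Round to cents?
#' @return USD per minute.
#' @examples
#' incremental_cost_per_minute(10712 / 104, 4901 / 101, 1362.4, 715) # 0.08
#' @export
incremental_cost_per_minute <- function(cost_i, cost_c, gain_i, gain_c,
                                        rounded = TRUE) {
  stopifnot_scalar_num(cost_i, "cost_i")
  stopifnot_scalar_num(cost_c, "cost_c")
  stopifnot_scalar_num(gain_i, "gain_i")
  stopifnot_scalar_num(gain_c, "gain_c")
  if (gain_i == gain_c) {
    stop("undefined incremental ratio: equal gains in both arms", call. = FALSE)
  }
  r <- (cost_i - cost_c) / (gain_i - gain_c)
  if (rounded) round_cents(r) else r
}

lookup_override <- function(overrides, keys, value_col) {
  if (is.null(overrides)) return(NA_real_)
  sel <- rep(TRUE, nrow(overrides))
  for (k in names(keys)) sel <- sel & overrides[[k]] == keys[[k]]
  if (!any(sel)) return(NA_real_)
  overrides[[value_col]][which(sel)[1]]
}

#' Fit the cost-effectiveness table for a two-arm trial
#'
#' The central analysis: combines an itemized [cost_ledger()] with per-arm
#' MVPA trajectories to produce, for every measure and horizon, the total and
#' per-month minute gains, the per-arm cost-per-minute ratios, and the
#' incremental cost-per-minute ratio of intervention over control. Ratios are
#' computed on unrounded per-person costs and unrounded gains and rounded to
#' cents only in the report table.
#'
#' Published inputs sometimes carry totals that differ slightly from what the
#' itemized ledger or the interpolated means reproduce (per-item rounding).
#' `gain_overrides` and `cost_overrides` let such printed totals replace the
#' internally computed values for specific cells, so downstream ratios match
#' a published analysis exactly; cells without an override are always
#' computed from the raw inputs.
#'
#' @param ledger A [cost_ledger()].
#' @param outcomes Named list of [outcome_series()] keyed `"<arm>.<measure>"`
#'   (as returned by [read_outcome_series()] or [summarize_to_series()]).
#'   Series for both arms of each measure analysed must be present.
#' @param measures Measures to tabulate (default: all present in `outcomes`).
#' @param horizons Analysis horizons in months (subset of `c(6, 12)`).
#' @param gain_overrides Optional `data.frame(arm, measure, horizon_months,
#'   total_minutes)` of printed gain totals.
#' @param cost_overrides Optional `data.frame(arm, horizon_months, total)` of
#'   printed arm cost totals.
#' @return Object of class `cea` with elements `gains`, `costs`, `per_arm`,
#'   `incremental` (long data.frames at full precision), `table` (the
#'   report-ready grid, money rounded to cents and gains to whole minutes),
#'   and the inputs.
#' @examples
#' fit <- cost_effectiveness(pasos_cost_ledger(), pasos_outcomes(),
#'                           gain_overrides = pasos_gain_overrides(),
#'                           cost_overrides = pasos_cost_overrides())
#' fit
#' @export
cost_effectiveness <- function(ledger, outcomes,
                               measures = NULL, horizons = c(6, 12),
                               gain_overrides = NULL, cost_overrides = NULL) {
  stopifnot(inherits(ledger, "cost_ledger"))
  if (!is.list(outcomes) || is.null(names(outcomes))) {
    stop("`outcomes` must be a named list of outcome series", call. = FALSE)
  }
  if (is.null(measures)) {
    measures <- intersect(MEASURES,
                          unique(vapply(outcomes, attr, "", "measure")))
  }
  if (length(measures) == 0) stop("no outcome series supplied", call. = FALSE)
  if (!all(horizons %in% c(6, 12))) {
    stop("`horizons` must be a subset of c(6, 12)", call. = FALSE)
  }
  for (m in measures) for (a in ARMS) series_key(outcomes, a, m)

  # Per-person minute gains, measure x arm x horizon
  gains <- expand.grid(measure = measures, arm = ARMS,
                       horizon_months = horizons,
                       stringsAsFactors = FALSE)
  gains$window_weeks <- gains$horizon_months * 26 / 6
  gains$total_minutes <- NA_real_
  gains$source <- "interpolated"
  for (i in seq_len(nrow(gains))) {
    ov <- lookup_override(gain_overrides,
                          list(arm = gains$arm[i], measure = gains$measure[i],
                               horizon_months = gains$horizon_months[i]),
                          "total_minutes")
    if (is.finite(ov)) {
      gains$total_minutes[i] <- ov
      gains$source[i] <- "override"
    } else {
      s <- series_key(outcomes, gains$arm[i], gains$measure[i])
      gains$total_minutes[i] <- cumulative_gain(s, 0, gains$window_weeks[i])
    }
  }
  gains$minutes_per_month <- gains$total_minutes / gains$horizon_months

  # Per-person costs, arm x horizon
  costs <- expand.grid(arm = ARMS, horizon_months = horizons,
                       stringsAsFactors = FALSE)
  costs$total <- NA_real_
  costs$source <- "ledger"
  for (i in seq_len(nrow(costs))) {
    ov <- lookup_override(cost_overrides,
                          list(arm = costs$arm[i],
                               horizon_months = costs$horizon_months[i]),
                          "total")
    if (is.finite(ov)) {
      costs$total[i] <- ov
      costs$source[i] <- "override"
    } else {
      costs$total[i] <- arm_total(ledger, costs$arm[i], costs$horizon_months[i])
    }
  }
  costs$n <- ledger$n[costs$arm]
  costs$per_person <- costs$total / costs$n

  per_arm <- gains[c("measure", "arm", "horizon_months")]
  per_arm$per_person_cost <- costs$per_person[
    match(paste(per_arm$arm, per_arm$horizon_months),
          paste(costs$arm, costs$horizon_months))]
  per_arm$cost_per_minute <- per_arm$per_person_cost / gains$total_minutes

  inc <- expand.grid(measure = measures, horizon_months = horizons,
                     stringsAsFactors = FALSE)
  pick <- function(df, m, a, h, col) {
    df[[col]][df$measure == m & df$arm == a & df$horizon_months == h]
  }
  inc$incremental_cost_per_minute <- NA_real_
  for (i in seq_len(nrow(inc))) {
    m <- inc$measure[i]; h <- inc$horizon_months[i]
    inc$incremental_cost_per_minute[i] <- incremental_cost_per_minute(
      pick(per_arm, m, "intervention", h, "per_person_cost"),
      pick(per_arm, m, "control", h, "per_person_cost"),
      pick(gains, m, "intervention", h, "total_minutes"),
      pick(gains, m, "control", h, "total_minutes"),
      rounded = FALSE
    )
  }
  inc$dominance <- inc$incremental_cost_per_minute < 0

  table <- inc[c("measure", "horizon_months")]
  for (a in ARMS) {
    table[[paste0("gain_", a)]] <- round(vapply(seq_len(nrow(table)),
      function(i) pick(gains, table$measure[i], a, table$horizon_months[i],
                       "total_minutes"), numeric(1)))
    table[[paste0("gain_per_month_", a)]] <- round(vapply(seq_len(nrow(table)),
      function(i) pick(gains, table$measure[i], a, table$horizon_months[i],
                       "minutes_per_month"), numeric(1)))
    table[[paste0("cost_per_minute_", a)]] <- round_cents(
      vapply(seq_len(nrow(table)),
        function(i) pick(per_arm, table$measure[i], a, table$horizon_months[i],
                         "cost_per_minute"), numeric(1)))
  }
  table$incremental_cost_per_minute <-
    round_cents(inc$incremental_cost_per_minute)

  structure(
    list(gains = gains, costs = costs, per_arm = per_arm, incremental = inc,
         table = table, ledger = ledger, outcomes = outcomes,
         measures = measures, horizons = horizons,
         gain_overrides = gain_overrides, cost_overrides = cost_overrides),
    class = "cea"
  )
}

#' @export
print.cea <- function(x, ...) {
  cat("Cost-effectiveness of MVPA gain (USD per minute)\n\n")
  for (m in x$measures) {
    cat(sprintf("Measure: %s\n", m))
    sub <- x$table[x$table$measure == m, ]
    for (i in seq_len(nrow(sub))) {
      cat(sprintf(
        paste0("  %2d months: gain %d min/person (I) vs %d (C);",
               " $%.2f vs $%.2f per minute; incremental $%.2f%s\n"),
        sub$horizon_months[i], sub$gain_intervention[i], sub$gain_control[i],
        sub$cost_per_minute_intervention[i], sub$cost_per_minute_control[i],
        sub$incremental_cost_per_minute[i],
        if (sub$incremental_cost_per_minute[i] < 0) " [dominance]" else ""))
    }
  }
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  cat("Per-arm costs:\n")
  print(summary(object$ledger), row.names = FALSE)
  cat("\nReport table:\n")
  print(object$table, row.names = FALSE)
  invisible(object$table)
}

#' @export
as.data.frame.cea <- function(x, ...) x$table
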