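#' One-way sensitivity adjustment of costs or effectiveness
#'
#' Rescales a single analysis input by a multiplier, leaving everything else
#' untouched:
#' \describe{
#'   \item{`staffing_costs`}{applied to a [cost_ledger()]: scales every
#'     personnel-time line item — training, intervention delivery, and routine
#'     website maintenance — in \emph{both} arms.}
#'   \item{`intervention_effectiveness`}{applied to a gains table (the
#'     `gains` element of a [cost_effectiveness()] fit, or any data.frame
#'     with a `total_minutes` column): scales the per-person minute gains in
#'     \emph{both} arms.}
#' }
#'
#' @param x A `cost_ledger` or a gains `data.frame`.
#' @param parameter `"staffing_costs"` or `"intervention_effectiveness"`.
#' @param multiplier Positive rescaling factor (e.g. `1.2` for +20\%).
#' @return `x` with the targeted quantities rescaled.
#' @examples
#' led20 <- apply_sensitivity(pasos_cost_ledger(), "staffing_costs", 1.2)
#' @export
apply_sensitivity <- function(x, parameter, multiplier) {
  parameter <- match.arg(parameter,
                         c("staffing_costs", "intervention_effectiveness"))
  stopifnot_scalar_num(multiplier, "multiplier")
  if (multiplier <= 0) stop("`multiplier` must be > 0", call. = FALSE)
  if (inherits(x, "cost_ledger")) {
    if (parameter != "staffing_costs") {
      stop("`intervention_effectiveness` applies to minute gains, ",
           "not a cost ledger", call. = FALSE)
    }
    sel <- x$items$category %in% STAFFING_CATEGORIES
    x$items$amount_6mo[sel] <- x$items$amount_6mo[sel] * multiplier
    x$items$amount_12mo[sel] <- x$items$amount_12mo[sel] * multiplier
    return(x)
  }
  if (is.data.frame(x) && "total_minutes" %in% names(x)) {
    if (parameter != "intervention_effectiveness") {
      stop("`staffing_costs` applies to a cost ledger, not minute gains",
           call. = FALSE)
    }
    x$total_minutes <- x$total_minutes * multiplier
    if ("minutes_per_month" %in% names(x)) {
      x$minutes_per_month <- x$minutes_per_month * multiplier
    }
    return(x)
  }
  stop("`x` must be a cost_ledger or a gains data.frame with a ",
       "`total_minutes` column", call. = FALSE)
}

staffing_subtotal <- function(ledger, arm, horizon_months) {
  col <- amount_col(horizon_months)
  sel <- ledger$items$arm == arm &
    ledger$items$category %in% STAFFING_CATEGORIES
  sum(ledger$items[[col]][sel])
}

#' One-way deterministic sensitivity table of incremental ratios
#'
#' Recomputes the incremental cost-per-minute ratio while rescaling a single
#' input at a time — staffing costs or intervention effectiveness, up and
#' down by `delta` — for every measure and horizon, alongside the standard
#' (unmodified) calculation. Staffing rescaling is applied to the ledger's
#' personnel line items (and, when printed cost totals are used as overrides,
#' the staffing delta is added onto the override, so the standard row stays
#' anchored to the published totals). Effectiveness rescaling multiplies both
#' arms' minute gains.
#'
#' @inheritParams cost_effectiveness
#' @param delta Relative perturbation (default `0.2` for ±20\%).
#' @return Object of class `cea_sensitivity`: a long `data.frame` with
#'   columns `scenario` (`standard`, `staffing_costs`,
#'   `intervention_effectiveness`), `multiplier`, `measure`,
#'   `horizon_months`, `incremental_cost_per_minute` (rounded to cents) and
#'   `unrounded`.
#' @examples
#' sensitivity_table(pasos_cost_ledger(), pasos_outcomes(),
#'                   gain_overrides = pasos_gain_overrides(),
#'                   cost_overrides = pasos_cost_overrides())
#' @export
sensitivity_table <- function(ledger, outcomes, delta = 0.2,
                              measures = NULL, horizons = c(6, 12),
                              gain_overrides = NULL, cost_overrides = NULL) {
  if (delta <= 0 || delta >= 1) stop("`delta` must be in (0, 1)", call. = FALSE)
  base <- cost_effectiveness(ledger, outcomes, measures, horizons,
                             gain_overrides, cost_overrides)

  refit_staffing <- function(m) {
    led2 <- apply_sensitivity(ledger, "staffing_costs", m)
    co2 <- cost_overrides
    if (!is.null(co2)) {
      for (i in seq_len(nrow(co2))) {
        co2$total[i] <- co2$total[i] +
          (m - 1) * staffing_subtotal(ledger, co2$arm[i], co2$horizon_months[i])
      }
    }
    cost_effectiveness(led2, outcomes, base$measures, horizons,
                       gain_overrides, co2)
  }
  refit_effectiveness <- function(m) {
    scaled <- apply_sensitivity(base$gains, "intervention_effectiveness", m)
    ov <- scaled[c("arm", "measure", "horizon_months", "total_minutes")]
    cost_effectiveness(ledger, outcomes, base$measures, horizons,
                       gain_overrides = ov, cost_overrides = cost_overrides)
  }

  scenarios <- list(
    list(name = "standard", multiplier = 1, fit = base),
    list(name = "staffing_costs", multiplier = 1 + delta,
         fit = refit_staffing(1 + delta)),
    list(name = "staffing_costs", multiplier = 1 - delta,
         fit = refit_staffing(1 - delta)),
    list(name = "intervention_effectiveness", multiplier = 1 + delta,
         fit = refit_effectiveness(1 + delta)),
    list(name = "intervention_effectiveness", multiplier = 1 - delta,
         fit = refit_effectiveness(1 - delta))
  )
  rows <- do.call(rbind, lapply(scenarios, function(sc) {
    inc <- sc$fit$incremental
    data.frame(scenario = sc$name, multiplier = sc$multiplier,
               measure = inc$measure, horizon_months = inc$horizon_months,
               incremental_cost_per_minute =
                 round_cents(inc$incremental_cost_per_minute),
               unrounded = inc$incremental_cost_per_minute,
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  structure(rows, class = c("cea_sensitivity", "data.frame"), delta = delta)
}

#' @export
print.cea_sensitivity <- function(x, ...) {
  delta <- attr(x, "delta")
  cat(sprintf(
    "One-way sensitivity of incremental cost per MVPA minute (±%d%%)\n\n",
    round(100 * delta)))
  combos <- unique(x[c("measure", "horizon_months")])
  header <- sprintf("%-34s", "Scenario")
  for (i in seq_len(nrow(combos))) {
    header <- paste0(header, sprintf("  %5s/%2dmo", substr(combos$measure[i], 1, 5),
                                     combos$horizon_months[i]))
  }
  cat(header, "\n")
  keys <- unique(x[c("scenario", "multiplier")])
  for (j in seq_len(nrow(keys))) {
    lab <- if (keys$scenario[j] == "standard") "standard calculation" else
      sprintf("%s %+d%%", keys$scenario[j],
              round(100 * (keys$multiplier[j] - 1)))
    line <- sprintf("%-34s", lab)
    for (i in seq_len(nrow(combos))) {
      v <- x$incremental_cost_per_minute[
        x$scenario == keys$scenario[j] & x$multiplier == keys$multiplier[j] &
        x$measure == combos$measure[i] &
        x$horizon_months == combos$horizon_months[i]]
      line <- paste0(line, sprintf("  $%8.2f", v))
    }
    cat(line, "\n")
  }
  invisible(x)
}
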