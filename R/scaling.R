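#' Split an arm's costs into fixed and per-person variable components
#'
#' Fixed costs (hardware, web hosting, technical support, training) do not
#' grow with enrollment; variable costs (materials, staff time to deliver the
#' intervention and maintain the website) accrue per participant. The
#' variable component is calibrated per person at the enrollment actually
#' observed in the trial.
#'
#' @param ledger A [cost_ledger()] whose items all carry a `scaling_role`.
#' @param arm Arm whose ledger is split (default `"intervention"`).
#' @param horizon_months 6 or 12.
#' @return List with `fixed_total` (USD), `variable_per_person` (USD/person),
#'   and `n_reference` (the arm size used for calibration).
#' @examples
#' split_fixed_variable(pasos_cost_ledger(), "intervention", 12)
#' @export
split_fixed_variable <- function(ledger, arm = "intervention",
                                 horizon_months = 12) {
  stopifnot(inherits(ledger, "cost_ledger"))
  arm <- match.arg(arm, ARMS)
  col <- amount_col(horizon_months)
  sub <- ledger$items[ledger$items$arm == arm, ]
  if (anyNA(sub$scaling_role)) {
    stop("ledger item '", sub$label[which(is.na(sub$scaling_role))[1]],
         "' has no scaling_role", call. = FALSE)
  }
  n <- ledger$n[[arm]]
  list(
    fixed_total = sum(sub[[col]][sub$scaling_role == "fixed"]),
    variable_per_person = sum(sub[[col]][sub$scaling_role == "variable"]) / n,
    n_reference = n
  )
}

#' Enrollment-scaling cost curve
#'
#' Models how the cost per person per month changes with the number of
#' participants enrolled: total cost at enrollment `n` is
#' `fixed_total + n * variable_per_person`, so the per-person-per-month cost
#' is `(fixed_total + n * variable_per_person) / (n * horizon_months)` —
#' strictly decreasing in `n` and approaching the asymptote
#' `variable_per_person / horizon_months`.
#'
#' @param ledger A [cost_ledger()], or `NULL` when `fixed_total` and
#'   `variable_per_person` are given directly.
#' @param arm Arm modelled (default `"intervention"`; the curve varies this
#'   arm's enrollment only).
#' @param horizon_months Horizon over which costs accrue (default 12).
#' @param fixed_total,variable_per_person Direct specification, bypassing the
#'   ledger split.
#' @return Object of class `scaling_curve` with fields `fixed_total`,
#'   `variable_per_person`, `horizon_months`, `n_reference`.
#' @examples
#' curve <- scaling_curve(pasos_cost_ledger())
#' predict(curve, n = c(50, 100, 200))
#' asymptotic_cost(curve)
#' @export
scaling_curve <- function(ledger = NULL, arm = "intervention",
                          horizon_months = 12,
                          fixed_total = NULL, variable_per_person = NULL) {
  if (horizon_months <= 0) stop("`horizon_months` must be > 0", call. = FALSE)
  n_ref <- NA_integer_
  if (!is.null(ledger)) {
    parts <- split_fixed_variable(ledger, arm, horizon_months)
    fixed_total <- parts$fixed_total
    variable_per_person <- parts$variable_per_person
    n_ref <- parts$n_reference
  }
  stopifnot_scalar_num(fixed_total, "fixed_total")
  stopifnot_scalar_num(variable_per_person, "variable_per_person")
  if (fixed_total < 0 || variable_per_person < 0) {
    stop("cost components must be >= 0", call. = FALSE)
  }
  structure(
    list(fixed_total = fixed_total, variable_per_person = variable_per_person,
         horizon_months = horizon_months, n_reference = n_ref, arm = arm),
    class = "scaling_curve"
  )
}

#' Cost per person per month at a given enrollment
#'
#' @param curve A [scaling_curve()].
#' @param n Number of participants enrolled (> 0); may be a vector.
#' @return USD per person per month (unrounded).
#' @examples
#' cost_per_person_per_month_at_n(scaling_curve(pasos_cost_ledger()), 100)
#' @export
cost_per_person_per_month_at_n <- function(curve, n) {
  stopifnot(inherits(curve, "scaling_curve"))
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("cannot evaluate the curve at `n` <= 0 participants", call. = FALSE)
  }
  (curve$fixed_total + n * curve$variable_per_person) /
    (n * curve$horizon_months)
}

#' @param object A [scaling_curve()].
#' @param n Enrollment grid at which to evaluate.
#' @param ... Unused.
#' @return `predict.scaling_curve`: `data.frame(n, cost_per_person_per_month)`.
#' @rdname scaling_curve
#' @export
predict.scaling_curve <- function(object, n, ...) {
  data.frame(n = n,
             cost_per_person_per_month =
               cost_per_person_per_month_at_n(object, n))
}

#' Asymptotic cost per person per month
#'
#' The large-enrollment limit of the scaling curve: fixed costs are spread
#' over infinitely many participants, leaving only
#' `variable_per_person / horizon_months`.
#'
#' @param curve A [scaling_curve()].
#' @return USD per person per month.
#' @export
asymptotic_cost <- function(curve) {
  stopifnot(inherits(curve, "scaling_curve"))
  curve$variable_per_person / curve$horizon_months
}

#' @export
print.scaling_curve <- function(x, ...) {
  cat(sprintf(
    paste0("Enrollment-scaling cost curve (%s arm, %d-month horizon)\n",
           "  fixed total: $%.2f\n  variable per person: $%.2f\n",
           "  asymptote: $%.2f per person per month\n"),
    x$arm, x$horizon_months, x$fixed_total, x$variable_per_person,
    asymptotic_cost(x)))
  if (is.finite(x$n_reference)) {
    cat(sprintf("  calibrated at n = %d\n", x$n_reference))
  }
  invisible(x)
}

#' @param from,to Enrollment range to draw.
#' @rdname scaling_curve
#' @export
plot.scaling_curve <- function(x, from = 25, to = 1000, ...) {
  n <- seq(from, to, length.out = 400)
  plot(n, cost_per_person_per_month_at_n(x, n), type = "l",
       xlab = "Participants enrolled",
       ylab = "Cost per person per month (USD)",
       main = sprintf("Scaling of delivery cost (%d-month horizon)",
                      x$horizon_months), ...)
  abline(h = asymptotic_cost(x), lty = 2)
  invisible(x)
}
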