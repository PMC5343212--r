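COST_CATEGORIES <- c(
  "personnel_training", "personnel_delivery", "website_maintenance",
  "website_hosting", "website_technical_support", "hardware", "materials"
)
COST_TIMINGS <- c("one_time", "recurring_monthly", "per_phase")
SCALING_ROLES <- c("fixed", "variable")
ARMS <- c("intervention", "control")

# Personnel categories rescaled together in the staffing sensitivity analysis:
# staff time covers training, delivery, and routine website maintenance.
STAFFING_CATEGORIES <- c(
  "personnel_training", "personnel_delivery", "website_maintenance"
)

#' Itemized per-arm cost ledger
#'
#' Assembles validated cost items into a ledger from the payer perspective.
#' Each item carries the cumulative amount charged by 6 months (the intensive
#' intervention phase) and by 12 months (through the maintenance phase), a
#' category, a timing profile, and its role in the enrollment-scaling model
#' (`fixed` costs do not grow with enrollment; `variable` costs accrue per
#' participant).
#'
#' @param items `data.frame` with columns `label`, `arm`
#'   (`"intervention"`/`"control"`), `category` (one of `personnel_training`,
#'   `personnel_delivery`, `website_maintenance`, `website_hosting`,
#'   `website_technical_support`, `hardware`, `materials`), `timing`
#'   (`one_time`, `recurring_monthly`, `per_phase`), `amount_6mo`,
#'   `amount_12mo` (cumulative USD), `scaling_role` (`fixed`/`variable`).
#' @param n_intervention,n_control Participants enrolled per arm (> 0).
#' @return An object of class `cost_ledger`: a list with elements `items`
#'   (validated data.frame) and `n` (named vector of arm sizes).
#' @examples
#' led <- pasos_cost_ledger()
#' arm_total(led, "intervention", 6)
#' @seealso [read_cost_ledger()], [arm_total()], [summary.cost_ledger()]
#' @export
cost_ledger <- function(items, n_intervention, n_control) {
  required <- c("label", "arm", "category", "timing",
                "amount_6mo", "amount_12mo", "scaling_role")
  if (!is.data.frame(items)) stop("`items` must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0) {
    stop("ledger is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  items <- items[required]
  if (nrow(items) > 0) {
    check_levels <- function(col, levels) {
      bad <- which(!(items[[col]] %in% levels))
      if (length(bad) > 0) {
        stop("row ", bad[1], ": invalid ", col, " '", items[[col]][bad[1]],
             "' (expected one of: ", paste(levels, collapse = ", "), ")",
             call. = FALSE)
      }
    }
    check_levels("arm", ARMS)
    check_levels("category", COST_CATEGORIES)
    check_levels("timing", COST_TIMINGS)
    check_levels("scaling_role", SCALING_ROLES)
    for (col in c("amount_6mo", "amount_12mo")) {
      bad <- which(!is.finite(items[[col]]) | items[[col]] < 0)
      if (length(bad) > 0) {
        stop("row ", bad[1], ": ", col, " must be a nonnegative number",
             call. = FALSE)
      }
    }
    bad <- which(items$amount_12mo < items$amount_6mo - 1e-9)
    if (length(bad) > 0) {
      stop("row ", bad[1], ": cumulative 12-month amount is below the ",
           "6-month amount", call. = FALSE)
    }
  }
  for (n in c(n_intervention, n_control)) {
    if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n <= 0 ||
        n != round(n)) {
      stop("arm sizes must be positive integers", call. = FALSE)
    }
  }
  structure(
    list(items = items,
         n = c(intervention = as.integer(n_intervention),
               control = as.integer(n_control))),
    class = "cost_ledger"
  )
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat("Cost ledger:", nrow(x$items), "items;",
      "n =", x$n[["intervention"]], "(intervention) /",
      x$n[["control"]], "(control)\n")
  for (arm in ARMS) {
    cat(sprintf("  %-12s 6 mo: $%s   12 mo: $%s\n", arm,
                format(round_dollars(arm_total(x, arm, 6)), big.mark = ","),
                format(round_dollars(arm_total(x, arm, 12)), big.mark = ",")))
  }
  invisible(x)
}

amount_col <- function(horizon_months) {
  if (!horizon_months %in% c(6, 12)) {
    stop("`horizon_months` must be 6 or 12", call. = FALSE)
  }
  if (horizon_months == 6) "amount_6mo" else "amount_12mo"
}

#' Total arm cost at a horizon
#'
#' Sums an arm's item amounts at the 6- or 12-month horizon. Because printed
#' cost tables round each item to whole dollars, reproduced column totals are
#' expected to agree with published ones only to within about $2.
#'
#' @param ledger A [cost_ledger()].
#' @param arm `"intervention"` or `"control"`.
#' @param horizon_months 6 or 12.
#' @return Total cost in USD.
#' @export
arm_total <- function(ledger, arm, horizon_months) {
  stopifnot(inherits(ledger, "cost_ledger"))
  arm <- match.arg(arm, ARMS)
  col <- amount_col(horizon_months)
  sum(ledger$items[[col]][ledger$items$arm == arm])
}

#' Per-category arm subtotals
#'
#' @inheritParams arm_total
#' @return Named numeric vector of USD subtotals over all categories
#'   (zero where an arm has no items).
#' @export
category_totals <- function(ledger, arm, horizon_months) {
  stopifnot(inherits(ledger, "cost_ledger"))
  arm <- match.arg(arm, ARMS)
  col <- amount_col(horizon_months)
  sub <- ledger$items[ledger$items$arm == arm, ]
  out <- setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)
  if (nrow(sub) > 0) {
    agg <- tapply(sub[[col]], factor(sub$category, levels = COST_CATEGORIES),
                  sum, default = 0)
    out[names(agg)] <- agg
  }
  out
}

#' Average cost per person per month
#'
#' @param total Total cost, USD.
#' @param n Number of participants (> 0).
#' @param horizon_months Months over which the total accrued (> 0).
#' @return USD per person per month, rounded to cents.
#' @examples
#' per_person_per_month(10712, 104, 6) # 17.17
#' @export
per_person_per_month <- function(total, n, horizon_months) {
  stopifnot_scalar_num(total, "total")
  stopifnot_scalar_num(n, "n")
  stopifnot_scalar_num(horizon_months, "horizon_months")
  if (n <= 0) stop("cannot divide by `n` = 0 participants", call. = FALSE)
  if (horizon_months <= 0) stop("`horizon_months` must be > 0", call. = FALSE)
  round_cents(total / n / horizon_months)
}

#' Per-arm cost summaries at both horizons
#'
#' @param object A [cost_ledger()].
#' @param ... Unused.
#' @return `data.frame` with one row per arm and horizon: `total`,
#'   `per_person`, `per_person_per_month` (per-person figures rounded to
#'   cents).
#' @export
summary.cost_ledger <- function(object, ...) {
  rows <- expand.grid(arm = ARMS, horizon_months = c(6, 12),
                      stringsAsFactors = FALSE)
  rows$total <- mapply(function(a, h) arm_total(object, a, h),
                       rows$arm, rows$horizon_months)
  rows$n <- object$n[rows$arm]
  rows$per_person <- round_cents(rows$total / rows$n)
  rows$per_person_per_month <- mapply(per_person_per_month,
                                      rows$total, rows$n, rows$horizon_months)
  rownames(rows) <- NULL
  rows
}

#' Read a personnel-rate table
#'
#' Reads a CSV of loaded annual salaries and converts each to a fully loaded
#' hourly rate: `loaded_annual_salary / hours_per_year`, rounded to cents,
#' then multiplied by `1 + overhead_frac`.
#'
#' @param path CSV with columns `label`, `loaded_annual_salary`,
#'   `overhead_frac`, `hours_per_year`.
#' @return `data.frame` with the input columns plus `hourly_loaded`.
#' @export
read_personnel_rates <- function(path) {
  rates <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("label", "loaded_annual_salary", "overhead_frac", "hours_per_year")
  missing_cols <- setdiff(required, names(rates))
  if (length(missing_cols) > 0) {
    stop("rates file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rates$hourly_loaded <- vapply(seq_len(nrow(rates)), function(i) {
    loaded_hourly_rate(
      hourly_rate(rates$loaded_annual_salary[i], 0, rates$hours_per_year[i]),
      rates$overhead_frac[i]
    )
  }, numeric(1))
  rates
}

#' Read a cost ledger from CSV
#'
#' Two schemas are accepted and detected from the header:
#' \describe{
#'   \item{amount-level}{columns `label, arm, category, timing, amount_6mo,
#'     amount_12mo, scaling_role` — amounts entered directly (e.g. a published
#'     cost table).}
#'   \item{basis-level}{columns `label, arm, category, timing, basis,
#'     quantity, quantity_12mo, rate_ref, unit_price, life_years, use_years,
#'     scaling_role` — amounts derived from resource use. `basis` is one of
#'     `hours` (quantity = task hours, costed at the loaded rate matching
#'     `rate_ref` in `rates`), `unit` (quantity x `unit_price`), or
#'     `purchase` (straight-line depreciation of `unit_price` over
#'     `life_years`, charging `use_years`). `quantity`/`quantity_12mo` are the
#'     cumulative quantities by 6 and 12 months; for `one_time` items
#'     `quantity_12mo` may be omitted (it defaults to `quantity`), and for
#'     `recurring_monthly` items `quantity` is per month and is multiplied by
#'     the horizon length.}
#' }
#'
#' @param path Ledger CSV (UTF-8, header row required).
#' @param rates Optional rate table from [read_personnel_rates()]; required
#'   for basis-level ledgers containing `hours` rows.
#' @param n_intervention,n_control Arm sizes.
#' @return A [cost_ledger()].
#' @export
read_cost_ledger <- function(path, rates = NULL,
                             n_intervention = 104, n_control = 101) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if ("amount_6mo" %in% names(raw)) {
    return(cost_ledger(raw, n_intervention, n_control))
  }
  required <- c("label", "arm", "category", "timing", "basis", "quantity",
                "scaling_role")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("ledger file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) {
    empty <- data.frame(label = character(), arm = character(),
                        category = character(), timing = character(),
                        amount_6mo = numeric(), amount_12mo = numeric(),
                        scaling_role = character())
    return(cost_ledger(empty, n_intervention, n_control))
  }
  bad <- which(!is.finite(raw$quantity) | raw$quantity < 0)
  if (length(bad) > 0) {
    stop("row ", bad[1], " ('", raw$label[bad[1]],
         "'): quantity must be nonnegative", call. = FALSE)
  }
  q6 <- raw$quantity
  q12 <- if ("quantity_12mo" %in% names(raw)) raw$quantity_12mo else
    rep(NA_real_, nrow(raw))
  item_amounts <- function(i, months) {
    qty <- switch(raw$timing[i],
      one_time = q6[i],
      recurring_monthly = q6[i] * months,
      per_phase = if (months == 6) q6[i] else {
        if (!is.finite(q12[i])) {
          stop("row ", i, " ('", raw$label[i],
               "'): per_phase items need `quantity_12mo`", call. = FALSE)
        }
        q12[i]
      },
      stop("row ", i, ": invalid timing '", raw$timing[i], "'", call. = FALSE)
    )
    switch(raw$basis[i],
      hours = {
        if (is.null(rates)) {
          stop("row ", i, " ('", raw$label[i],
               "'): hours-based items need a `rates` table", call. = FALSE)
        }
        j <- match(raw$rate_ref[i], rates$label)
        if (is.na(j)) {
          stop("row ", i, ": unknown rate_ref '", raw$rate_ref[i], "'",
               call. = FALSE)
        }
        personnel_cost(qty, rates$hourly_loaded[j])
      },
      unit = round_cents(qty * raw$unit_price[i]),
      purchase = qty * straight_line_depreciation(raw$unit_price[i],
                                                  raw$life_years[i],
                                                  raw$use_years[i]),
      stop("row ", i, ": invalid basis '", raw$basis[i], "'", call. = FALSE)
    )
  }
  items <- data.frame(
    label = raw$label, arm = raw$arm, category = raw$category,
    timing = raw$timing,
    amount_6mo = vapply(seq_len(nrow(raw)), item_amounts, numeric(1), months = 6),
    amount_12mo = vapply(seq_len(nrow(raw)), item_amounts, numeric(1), months = 12),
    scaling_role = raw$scaling_role,
    stringsAsFactors = FALSE
  )
  cost_ledger(items, n_intervention, n_control)
}

#' Write a ledger's items to CSV (amount-level schema)
#'
#' @param ledger A [cost_ledger()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_ledger <- function(ledger, path) {
  stopifnot(inherits(ledger, "cost_ledger"))
  write.csv(ledger$items, path, row.names = FALSE)
  invisible(path)
}
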