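#' Hourly wage from an annual salary
#'
#' Converts an annual salary to an hourly rate, optionally loading it with a
#' fringe-benefit fraction first. When a fully loaded annual figure is
#' supplied directly (salary plus benefits already included), pass
#' `fringe_frac = 0`. The result is rounded to cents.
#'
#' @param annual_salary Annual salary in USD/year (base, or loaded if
#'   `fringe_frac = 0`).
#' @param fringe_frac Fringe-benefit fraction added to salary (e.g. `0.44`
#'   for 44\% benefits). Must lie in `[0, 1)`.
#' @param hours_per_year Work hours per year the salary covers. The package
#'   convention is a 2000-hour work year.
#' @return Hourly rate in USD/hour, rounded to cents.
#' @examples
#' hourly_rate(86520, 0, 2000) # 43.26
#' hourly_rate(56153, 0, 2000) # 28.08
#' @seealso [loaded_hourly_rate()] to add overhead, [personnel_cost()].
#' @export
hourly_rate <- function(annual_salary, fringe_frac = 0, hours_per_year = 2000) {
  stopifnot_scalar_num(annual_salary, "annual_salary")
  stopifnot_scalar_num(fringe_frac, "fringe_frac")
  stopifnot_scalar_num(hours_per_year, "hours_per_year")
  if (annual_salary < 0) stop("`annual_salary` must be >= 0", call. = FALSE)
  if (fringe_frac < 0 || fringe_frac >= 1) {
    stop("`fringe_frac` must be in [0, 1)", call. = FALSE)
  }
  if (hours_per_year <= 0) stop("`hours_per_year` must be > 0", call. = FALSE)
  round_cents(annual_salary * (1 + fringe_frac) / hours_per_year)
}

#' Load an hourly rate with overhead
#'
#' Applies an overhead multiplier (e.g. shared space and administration) to a
#' base hourly wage. Unlike [hourly_rate()] the result is not rounded, so the
#' loaded rate can be carried at full precision into [personnel_cost()].
#'
#' @param base_hourly Base hourly wage, USD/hour.
#' @param overhead_frac Overhead fraction (e.g. `0.10` for 10\%). Must be
#'   >= 0.
#' @return Loaded hourly rate, USD/hour.
#' @examples
#' loaded_hourly_rate(43.26, 0.10) # 47.586
#' @export
loaded_hourly_rate <- function(base_hourly, overhead_frac = 0.10) {
  stopifnot_scalar_num(base_hourly, "base_hourly")
  stopifnot_scalar_num(overhead_frac, "overhead_frac")
  if (base_hourly < 0) stop("`base_hourly` must be >= 0", call. = FALSE)
  if (overhead_frac < 0) stop("`overhead_frac` must be >= 0", call. = FALSE)
  base_hourly * (1 + overhead_frac)
}

#' Personnel cost for logged task time
#'
#' @param hours Task hours (>= 0). May be a vector; costs are itemwise.
#' @param loaded_rate Fully loaded hourly rate, USD/hour.
#' @return Cost in USD, rounded to cents.
#' @examples
#' personnel_cost(9.9, loaded_hourly_rate(43.26, 0.10)) # 471.10
#' @export
personnel_cost <- function(hours, loaded_rate) {
  if (!is.numeric(hours) || any(!is.finite(hours))) {
    stop("`hours` must be finite numeric", call. = FALSE)
  }
  stopifnot_scalar_num(loaded_rate, "loaded_rate")
  if (any(hours < 0)) stop("`hours` must be >= 0", call. = FALSE)
  if (loaded_rate < 0) stop("`loaded_rate` must be >= 0", call. = FALSE)
  round_cents(hours * loaded_rate)
}

#' Straight-line depreciation of a hardware purchase
#'
#' Allocates a purchase price evenly over its depreciation life and charges
#' the years actually used: `price * use_years / life_years`.
#'
#' @param purchase_price Purchase price, USD (>= 0).
#' @param life_years Depreciation period in years (> 0).
#' @param use_years Years of use charged to the program; must satisfy
#'   `0 < use_years <= life_years`.
#' @return Depreciated cost, USD.
#' @examples
#' straight_line_depreciation(700, 5, 3) # 420
#' @export
straight_line_depreciation <- function(purchase_price, life_years = 5, use_years = 3) {
  stopifnot_scalar_num(purchase_price, "purchase_price")
  stopifnot_scalar_num(life_years, "life_years")
  stopifnot_scalar_num(use_years, "use_years")
  if (purchase_price < 0) stop("`purchase_price` must be >= 0", call. = FALSE)
  if (use_years <= 0) stop("`use_years` must be > 0", call. = FALSE)
  if (use_years > life_years) {
    stop("`use_years` must not exceed `life_years`", call. = FALSE)
  }
  purchase_price * use_years / life_years
}
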