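test_that("the packaged cost table reproduces the published column totals", {
  led <- pasos_cost_ledger()
  expect_equal(arm_total(led, "intervention", 6), 10712)
  expect_lte(abs(arm_total(led, "control", 6) - 4900), 2)
  expect_lte(abs(arm_total(led, "control", 12) - 7634), 2)
  # the 12-month intervention column includes the $150 video row
  expect_equal(arm_total(led, "intervention", 12), 14931)
})

test_that("arm totals are additive over category subtotals", {
  led <- pasos_cost_ledger()
  for (arm in c("intervention", "control")) {
    for (h in c(6, 12)) {
      expect_equal(sum(category_totals(led, arm, h)), arm_total(led, arm, h))
    }
  }
})

test_that("cumulative amounts are monotone in the horizon", {
  led <- pasos_cost_ledger()
  for (arm in c("intervention", "control")) {
    expect_gte(arm_total(led, arm, 12), arm_total(led, arm, 6))
  }
})

test_that("per-person-per-month reproduces published unit costs and inverts", {
  expect_equal(per_person_per_month(10712, 104, 6), 17.17)
  expect_equal(per_person_per_month(4900, 101, 6), 8.09)
  expect_equal(per_person_per_month(7634, 101, 12), 6.30)
  expect_equal(per_person_per_month(0, 104, 6), 0)
  set.seed(3)
  for (i in 1:25) {
    total <- runif(1, 0, 50000)
    n <- sample(10:500, 1)
    m <- sample(c(6, 12), 1)
    ppm <- per_person_per_month(total, n, m)
    # identity holds to within half a cent per participant-month
    expect_lte(abs(ppm * n * m - total), 0.005 * n * m + 1e-9)
  }
  expect_error(per_person_per_month(100, 0, 6), "n")
})

test_that("an empty ledger totals zero and unknown arms are rejected", {
  empty <- cost_ledger(pasos_cost_ledger()$items[0, ], 10, 10)
  expect_equal(arm_total(empty, "intervention", 6), 0)
  expect_error(arm_total(pasos_cost_ledger(), "placebo", 6))
})

test_that("ledger validation names the offending row and field", {
  items <- pasos_cost_ledger()$items
  bad <- items
  bad$amount_6mo[3] <- -5
  expect_error(cost_ledger(bad, 104, 101), "row 3.*amount_6mo")
  bad <- items
  bad$category[2] <- "advertising"
  expect_error(cost_ledger(bad, 104, 101), "row 2.*category")
  bad <- items
  bad$amount_12mo[1] <- bad$amount_6mo[1] - 10
  expect_error(cost_ledger(bad, 104, 101), "12-month")
  expect_error(cost_ledger(items[, -5], 104, 101), "missing column")
})

test_that("a basis-level ledger derives amounts from rates and prices", {
  rates <- pasos_personnel_rates()
  expect_equal(rates$hourly_loaded, c(47.586, 30.888))
  led <- read_cost_ledger(
    system.file("extdata", "pasos_costs_basis.csv", package = "activecost"),
    rates = rates, n_intervention = 104, n_control = 101)
  items <- led$items
  pick <- function(lab, arm) items[items$label == lab & items$arm == arm, ]
  expect_equal(pick("Training", "intervention")$amount_6mo, 471.10)
  expect_equal(pick("Computer", "intervention")$amount_6mo, 420)
  expect_equal(pick("Printer", "control")$amount_12mo, 240)
  expect_equal(pick("Website hosting", "intervention")$amount_6mo, 450)
  expect_equal(pick("Website hosting", "intervention")$amount_12mo, 900)
  expect_equal(pick("Technical support", "control")$amount_12mo, 2280)
  expect_equal(pick("Pedometers", "intervention")$amount_6mo, 1300)
  expect_equal(pick("Video library", "intervention")$amount_12mo, 150)
  # derived column totals track the published ones to item-rounding error
  expect_lte(abs(arm_total(led, "intervention", 6) - 10712), 2)
  expect_lte(abs(arm_total(led, "control", 6) - 4900), 2)
})

test_that("ledger CSV write/read round-trip is lossless", {
  led <- pasos_cost_ledger()
  tmp <- tempfile(fileext = ".csv")
  write_cost_ledger(led, tmp)
  led2 <- read_cost_ledger(tmp, n_intervention = 104, n_control = 101)
  expect_equal(led2$items, led$items)
  expect_equal(led2$n, led$n)
})

test_that("basis-level schema errors carry a location", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c(
    "label,arm,category,timing,basis,quantity,rate_ref,unit_price,life_years,use_years,scaling_role",
    "Call,intervention,personnel_delivery,one_time,hours,-2,research_associate,,,,variable"
  ), tmp)
  expect_error(read_cost_ledger(tmp, pasos_personnel_rates()),
               "row 1.*quantity")
  writeLines(c(
    "label,arm,category,timing,basis,quantity,rate_ref,unit_price,life_years,use_years,scaling_role",
    "Call,intervention,personnel_delivery,one_time,hours,2,unknown_role,,,,variable"
  ), tmp)
  expect_error(read_cost_ledger(tmp, pasos_personnel_rates()),
               "rate_ref")
})
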