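pasos_sensitivity <- function(delta = 0.2) {
  inp <- pasos_inputs_all()
  sensitivity_table(inp$ledger, inp$outcomes, delta = delta,
                    gain_overrides = inp$gains, cost_overrides = inp$costs)
}

cell <- function(tab, scenario, multiplier, measure, horizon) {
  tab$incremental_cost_per_minute[
    tab$scenario == scenario & abs(tab$multiplier - multiplier) < 1e-9 &
      tab$measure == measure & tab$horizon_months == horizon]
}

test_that("identity multiplier leaves ledger and gains unchanged", {
  led <- pasos_cost_ledger()
  expect_equal(apply_sensitivity(led, "staffing_costs", 1)$items, led$items)
  gains <- data.frame(total_minutes = c(100, 200))
  expect_equal(apply_sensitivity(gains, "intervention_effectiveness", 1), gains)
  expect_error(apply_sensitivity(led, "intervention_effectiveness", 1.2),
               "cost ledger")
  expect_error(apply_sensitivity(led, "advertising", 1.2))
})

test_that("staffing rescaling touches only personnel-time items, both arms", {
  led <- pasos_cost_ledger()
  up <- apply_sensitivity(led, "staffing_costs", 1.2)
  staffed <- led$items$category %in% c("personnel_training",
                                       "personnel_delivery",
                                       "website_maintenance")
  expect_equal(up$items$amount_6mo[staffed], 1.2 * led$items$amount_6mo[staffed])
  expect_equal(up$items$amount_6mo[!staffed], led$items$amount_6mo[!staffed])
  expect_setequal(unique(led$items$arm[staffed]), c("intervention", "control"))
})

test_that("the standard row reproduces the baseline incremental ratios", {
  inp <- pasos_inputs_all()
  base <- cost_effectiveness(inp$ledger, inp$outcomes,
                             gain_overrides = inp$gains,
                             cost_overrides = inp$costs)
  tab <- pasos_sensitivity()
  std <- tab[tab$scenario == "standard", ]
  expect_equal(std$unrounded, base$incremental$incremental_cost_per_minute)
})

test_that("the ±20% grid reproduces the published sensitivity analysis", {
  tab <- pasos_sensitivity()
  expect_equal(cell(tab, "standard", 1.0, "par", 6), 0.08)
  expect_equal(cell(tab, "standard", 1.0, "accelerometer", 6), 0.16)
  expect_equal(cell(tab, "standard", 1.0, "par", 12), 0.04)
  expect_equal(cell(tab, "standard", 1.0, "accelerometer", 12), 0.08)
  expect_equal(cell(tab, "staffing_costs", 1.2, "par", 6), 0.10)
  expect_equal(cell(tab, "staffing_costs", 1.2, "accelerometer", 6), 0.19)
  expect_equal(cell(tab, "staffing_costs", 1.2, "par", 12), 0.04)
  expect_equal(cell(tab, "staffing_costs", 1.2, "accelerometer", 12), 0.10)
  expect_equal(cell(tab, "staffing_costs", 0.8, "par", 6), 0.07)
  expect_equal(cell(tab, "staffing_costs", 0.8, "accelerometer", 6), 0.14)
  expect_equal(cell(tab, "staffing_costs", 0.8, "par", 12), 0.03)
  expect_equal(cell(tab, "staffing_costs", 0.8, "accelerometer", 12), 0.07)
  expect_equal(cell(tab, "intervention_effectiveness", 1.2, "par", 6), 0.07)
  expect_equal(cell(tab, "intervention_effectiveness", 1.2, "accelerometer", 6),
               0.13)
  expect_equal(cell(tab, "intervention_effectiveness", 1.2, "par", 12), 0.03)
  expect_equal(cell(tab, "intervention_effectiveness", 1.2, "accelerometer", 12),
               0.07)
  expect_equal(cell(tab, "intervention_effectiveness", 0.8, "par", 6), 0.11)
  expect_equal(cell(tab, "intervention_effectiveness", 0.8, "accelerometer", 6),
               0.20)
  expect_equal(cell(tab, "intervention_effectiveness", 0.8, "par", 12), 0.05)
})

test_that("effectiveness rescaling is exactly reciprocal on the ICER", {
  inp <- pasos_inputs_all()
  for (delta in c(0.1, 0.2, 0.35)) {
    tab <- sensitivity_table(inp$ledger, inp$outcomes, delta = delta,
                             gain_overrides = inp$gains,
                             cost_overrides = inp$costs)
    std <- tab$unrounded[tab$scenario == "standard"]
    up <- tab$unrounded[tab$scenario == "intervention_effectiveness" &
                          tab$multiplier == 1 + delta]
    dn <- tab$unrounded[tab$scenario == "intervention_effectiveness" &
                          tab$multiplier == 1 - delta]
    expect_equal(up, std / (1 + delta))
    expect_equal(dn, std / (1 - delta))
  }
})

test_that("staffing rescaling shifts only the ICER numerator, proportionally", {
  inp <- pasos_inputs_all()
  staffing_diff <- function(h) {
    staffed <- c("personnel_training", "personnel_delivery",
                 "website_maintenance")
    col <- if (h == 6) "amount_6mo" else "amount_12mo"
    it <- inp$ledger$items
    sum(it[[col]][it$arm == "intervention" & it$category %in% staffed]) / 104 -
      sum(it[[col]][it$arm == "control" & it$category %in% staffed]) / 101
  }
  for (m_mult in c(0.8, 1.2, 1.5)) {
    tab <- sensitivity_table(inp$ledger, inp$outcomes,
                             delta = abs(m_mult - 1),
                             gain_overrides = inp$gains,
                             cost_overrides = inp$costs)
    std <- tab[tab$scenario == "standard", ]
    stf <- tab[tab$scenario == "staffing_costs" &
                 abs(tab$multiplier - m_mult) < 1e-9, ]
    gains <- cost_effectiveness(inp$ledger, inp$outcomes,
                                gain_overrides = inp$gains,
                                cost_overrides = inp$costs)$gains
    for (i in seq_len(nrow(std))) {
      h <- std$horizon_months[i]
      mm <- std$measure[i]
      dg <- gains$total_minutes[gains$measure == mm & gains$arm ==
              "intervention" & gains$horizon_months == h] -
            gains$total_minutes[gains$measure == mm & gains$arm ==
              "control" & gains$horizon_months == h]
      expect_equal(stf$unrounded[stf$measure == mm & stf$horizon_months == h] -
                     std$unrounded[i],
                   (m_mult - 1) * staffing_diff(h) / dg)
    }
  }
})
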