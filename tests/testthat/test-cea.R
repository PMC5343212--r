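test_that("per-arm cost-per-minute ratios reproduce the published values", {
  expect_equal(cost_per_minute(10712 / 104, 1362.4), 0.08)
  expect_equal(cost_per_minute(10712 / 104, 523), 0.20)
  expect_equal(cost_per_minute(0, 1000), 0)
  expect_error(cost_per_minute(100, 0), "zero")
})

test_that("incremental ratios reproduce the published values", {
  expect_equal(incremental_cost_per_minute(103.00, 48.51, 1362.4, 715), 0.08)
  expect_equal(incremental_cost_per_minute(103.00, 48.51, 523, 186), 0.16)
  expect_equal(incremental_cost_per_minute(50, 50, 100, 10), 0)
  expect_error(incremental_cost_per_minute(10, 5, 100, 100), "equal gains")
})

test_that("the fitted table matches a cell-by-cell brute-force recomputation", {
  inp <- pasos_inputs_all()
  fit <- cost_effectiveness(inp$ledger, inp$outcomes,
                            gain_overrides = inp$gains,
                            cost_overrides = inp$costs)
  for (m in c("par", "accelerometer")) {
    for (h in c(6, 12)) {
      weeks <- h * 26 / 6
      gain <- sapply(c(intervention = "intervention", control = "control"),
        function(a) {
          ov <- inp$gains[inp$gains$arm == a & inp$gains$measure == m &
                            inp$gains$horizon_months == h, "total_minutes"]
          if (length(ov) == 1) ov else
            cumulative_gain(inp$outcomes[[paste0(a, ".", m)]], 0, weeks)
        })
      cost <- sapply(c(intervention = "intervention", control = "control"),
        function(a) {
          ov <- inp$costs[inp$costs$arm == a &
                            inp$costs$horizon_months == h, "total"]
          (if (length(ov) == 1) ov else arm_total(inp$ledger, a, h)) /
            inp$ledger$n[[a]]
        })
      row <- fit$table[fit$table$measure == m & fit$table$horizon_months == h, ]
      expect_equal(row$gain_intervention, round(gain[["intervention"]]))
      expect_equal(row$gain_control, round(gain[["control"]]))
      expect_equal(row$gain_per_month_intervention,
                   round(gain[["intervention"]] / h))
      expect_equal(row$cost_per_minute_intervention,
                   round(cost[["intervention"]] / gain[["intervention"]], 2))
      expect_equal(row$cost_per_minute_control,
                   round(cost[["control"]] / gain[["control"]], 2))
      expect_equal(row$incremental_cost_per_minute,
                   round((cost[["intervention"]] - cost[["control"]]) /
                           (gain[["intervention"]] - gain[["control"]]), 2))
    }
  }
})

test_that("ratios are exactly equivariant in cost scale and gain scale", {
  set.seed(31)
  for (i in 1:20) {
    ci <- runif(1, 10, 300); cc <- runif(1, 10, 300)
    gi <- runif(1, 100, 5000); gc <- runif(1, 1, 99)
    k <- runif(1, 0.1, 10); m <- runif(1, 0.1, 10)
    expect_equal(incremental_cost_per_minute(k * ci, k * cc, gi, gc,
                                             rounded = FALSE),
                 k * incremental_cost_per_minute(ci, cc, gi, gc,
                                                 rounded = FALSE))
    expect_equal(incremental_cost_per_minute(ci, cc, m * gi, m * gc,
                                             rounded = FALSE),
                 incremental_cost_per_minute(ci, cc, gi, gc,
                                             rounded = FALSE) / m)
    expect_equal(cost_per_minute(k * ci, gi, rounded = FALSE),
                 k * cost_per_minute(ci, gi, rounded = FALSE))
  }
})

test_that("a zero-cost ledger yields all-zero per-arm ratios", {
  inp <- pasos_inputs_all()
  zero <- inp$ledger
  zero$items$amount_6mo <- 0
  zero$items$amount_12mo <- 0
  fit <- cost_effectiveness(zero, inp$outcomes)
  expect_true(all(fit$table$cost_per_minute_intervention == 0))
  expect_true(all(fit$table$cost_per_minute_control == 0))
})

test_that("a missing series is reported by arm and measure", {
  inp <- pasos_inputs_all()
  expect_error(
    cost_effectiveness(inp$ledger, inp$outcomes[c("intervention.par",
                                                  "control.par")],
                       measures = "accelerometer"),
    "intervention arm, accelerometer")
})

test_that("negative incremental ratios carry a dominance flag", {
  inp <- pasos_inputs_all()
  # make the intervention cheaper while still more effective
  co <- inp$costs
  co$total[co$arm == "intervention"] <- 100
  fit <- cost_effectiveness(inp$ledger, inp$outcomes, cost_overrides = co)
  expect_true(all(fit$incremental$dominance))
})
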