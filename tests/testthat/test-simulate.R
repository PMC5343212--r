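test_that("simulation is deterministic under a fixed seed", {
  cfg <- trial_sim_config()
  expect_identical(simulate_trial(cfg, seed = 9), simulate_trial(cfg, seed = 9))
  expect_identical(simulate_staff_log(cfg, seed = 9),
                   simulate_staff_log(cfg, seed = 9))
})

test_that("generated minutes are nonnegative and respect eligibility", {
  rec <- simulate_trial(trial_sim_config(), seed = 2)
  vals <- as.matrix(rec[grep("_w", names(rec))])
  expect_true(all(vals >= 0, na.rm = TRUE))
  expect_true(all(rec$par_w0 < 60))
  # dropouts lack post-baseline values; completers have them all
  post <- c("par_w26", "par_w52", "accelerometer_w26", "accelerometer_w52")
  expect_true(all(is.na(as.matrix(rec[!rec$completed, post]))))
  expect_true(all(!is.na(as.matrix(rec[rec$completed, post]))))
})

test_that("the completer fraction recovers the configured dropout", {
  cfg <- trial_sim_config(n_per_arm = c(intervention = 10000, control = 10000))
  rec <- simulate_trial(cfg, seed = 3)
  se <- sqrt(0.161 * 0.839 / nrow(rec))
  expect_lt(abs(mean(rec$completed) - 0.839), 3 * se)
})

test_that("completer means and SDs recover the configured distributions", {
  cfg <- trial_sim_config(n_per_arm = c(intervention = 5000, control = 5000))
  rec <- simulate_trial(cfg, seed = 42)
  ser <- summarize_to_series(rec)
  for (arm in c("intervention", "control")) {
    for (m in c("par", "accelerometer")) {
      target <- cfg$timepoints[[arm]][[m]]
      s <- ser[[paste(arm, m, sep = ".")]]
      n <- s$n[1]
      expect_lt(max(abs(s$mean_weekly_minutes - target$mean) /
                      (target$sd / sqrt(n))), 3)
      # SDs within 10% of configured
      expect_lt(max(abs(s$sd / target$sd - 1)), 0.1)
    }
  }
})

test_that("dropout is independent of baseline activity", {
  cfg <- trial_sim_config(n_per_arm = c(intervention = 10000, control = 10000))
  rec <- simulate_trial(cfg, seed = 4)
  for (arm in c("intervention", "control")) {
    sub <- rec[rec$arm == arm, ]
    comp <- sub$par_w0[sub$completed]
    drop <- sub$par_w0[!sub$completed]
    se <- sd(sub$par_w0) * sqrt(1 / length(comp) + 1 / length(drop))
    expect_lt(abs(mean(comp) - mean(drop)), 3 * se)
  }
})

test_that("degenerate zero-variance configs reproduce the means exactly", {
  tp <- trial_sim_config()$timepoints
  for (arm in names(tp)) for (m in names(tp[[arm]])) tp[[arm]][[m]]$sd <- 0
  cfg <- trial_sim_config(n_per_arm = c(intervention = 20, control = 20),
                          timepoints = tp, dropout = 0)
  ser <- summarize_to_series(simulate_trial(cfg, seed = 5))
  for (arm in names(tp)) for (m in names(tp[[arm]])) {
    s <- ser[[paste(arm, m, sep = ".")]]
    expect_equal(s$mean_weekly_minutes, tp[[arm]][[m]]$mean)
    expect_equal(s$sd, rep(0, 3))
    expect_equal(s$n, rep(20, 3))
  }
})

test_that("an unattainable target distribution is a configuration error", {
  expect_error(activecost:::censored_normal_params(80, 5, upper = 60),
               "ceiling")
})

test_that("summarizing requires completers in each arm", {
  cfg <- trial_sim_config(n_per_arm = c(intervention = 5, control = 5))
  rec <- simulate_trial(cfg, seed = 6)
  rec$completed[rec$arm == "control"] <- FALSE
  expect_error(summarize_to_series(rec), "completers")
})

test_that("the staff log reproduces published delivery-cost structure", {
  log <- simulate_staff_log(trial_sim_config(), seed = 1)
  costs <- staff_log_cost(log, pasos_personnel_rates())
  delivery6 <- costs$cost[costs$arm == "intervention" &
                            costs$category == "personnel_delivery" &
                            costs$phase == 1]
  expect_lt(abs(delivery6 - 5674), 10)
  training <- costs$cost[costs$arm == "intervention" &
                           costs$category == "personnel_training"]
  expect_lt(abs(training - 471), 2)
  ctrl6 <- costs$cost[costs$arm == "control" &
                        costs$category == "personnel_delivery" &
                        costs$phase == 1]
  expect_lt(abs(ctrl6 - 1976), 10)
})

test_that("an empty task catalog yields an empty log with zero cost", {
  cfg <- trial_sim_config(staff_tasks = trial_sim_config()$staff_tasks[0, ])
  log <- simulate_staff_log(cfg, seed = 1)
  expect_equal(nrow(log), 0)
  expect_equal(nrow(staff_log_cost(log, pasos_personnel_rates())), 0)
})

test_that("unknown rate labels in a staff log are a configuration error", {
  log <- simulate_staff_log(trial_sim_config(), seed = 1)
  log$rate_label[1] <- "volunteer"
  expect_error(staff_log_cost(log, pasos_personnel_rates()), "volunteer")
})

test_that("the synthetic pipeline recovers the ICER implied by its config", {
  cfg <- trial_sim_config(n_per_arm = c(intervention = 5000, control = 5000))
  ser <- summarize_to_series(simulate_trial(cfg, seed = 7))
  led <- pasos_cost_ledger()
  fit <- cost_effectiveness(led, ser, cost_overrides = pasos_cost_overrides())
  # ICER implied by the configured means (PAR, 6 months)
  implied <- (10712 / 104 - 4900 / 101) /
    ((112.8 - 8.0) / 2 * 26 - (63.5 - 8.5) / 2 * 26)
  got <- fit$incremental$incremental_cost_per_minute[
    fit$incremental$measure == "par" & fit$incremental$horizon_months == 6]
  expect_lt(abs(got - implied) / implied, 0.05)
})
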