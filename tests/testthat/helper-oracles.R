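# Independent brute-force oracles used to cross-check the implementation.

# Midpoint Riemann sum of (interpolated weekly minutes - baseline) over
# [start, end] at a fine step; independent of the trapezoid path.
riemann_gain <- function(series, start_week, end_week, step = 0.001) {
  mids <- seq(start_week + step / 2, end_week - step / 2, by = step)
  vals <- interpolate_weekly_minutes(series, mids)
  sum((vals - series$mean_weekly_minutes[1]) * step)
}

# Brute-force bout scorer: explicit minute-by-minute scan for maximal runs
# of worn, above-threshold minutes; no interruption allowance.
brute_force_mvpa <- function(counts, worn = rep(TRUE, length(counts)),
                             threshold = 1952, min_bout = 10) {
  qualifies <- worn & counts >= threshold
  total <- 0L
  run <- 0L
  for (i in seq_along(qualifies)) {
    if (qualifies[i]) {
      run <- run + 1L
    } else {
      if (run >= min_bout) total <- total + run
      run <- 0L
    }
  }
  if (run >= min_bout) total <- total + run
  total
}

random_series <- function(arm = "intervention", measure = "par") {
  k <- sample(2:5, 1)
  weeks <- c(0, sort(sample(1:80, k - 1)))
  outcome_series(arm, measure, weeks, runif(k, 0, 200))
}

# Per-arm completer series built directly from configured means (degenerate,
# zero-variance draws) for end-to-end identities.
pasos_inputs_all <- function() {
  list(ledger = pasos_cost_ledger(), outcomes = pasos_outcomes(),
       gains = pasos_gain_overrides(), costs = pasos_cost_overrides())
}
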