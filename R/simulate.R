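# Moments of X = max(0, L), L ~ N(mu, sigma), optionally conditioned on
# L < upper (the eligibility ceiling). Closed-form normal partial moments.
censored_normal_moments <- function(mu, sigma, upper = Inf) {
  if (sigma <= 0) {
    x <- max(0, mu)
    return(c(mean = if (mu < upper) x else NaN, sd = 0))
  }
  a <- -mu / sigma
  b <- (upper - mu) / sigma
  p_ok <- pnorm(b)
  dphi <- dnorm(a) - dnorm(b)
  dPhi <- pnorm(b) - pnorm(a)
  bphib <- if (is.finite(b)) b * dnorm(b) else 0
  m1 <- (mu * dPhi + sigma * dphi) / p_ok
  m2 <- (mu^2 * dPhi + 2 * mu * sigma * dphi +
           sigma^2 * (dPhi + a * dnorm(a) - bphib)) / p_ok
  c(mean = m1, sd = sqrt(max(0, m2 - m1^2)))
}

# Solve for latent (mu, sigma) so that max(0, N(mu, sigma)) | N < upper has
# the requested mean and SD. Activity minutes are zero-censored (a point mass
# of fully inactive weeks), which - unlike zero-truncation - can reproduce
# the overdispersed baselines seen in underactive samples (SD >> mean).
censored_normal_params <- function(target_mean, target_sd, upper = Inf) {
  if (target_mean < 0) stop("target mean must be >= 0", call. = FALSE)
  if (is.finite(upper) && target_mean >= upper) {
    stop("configuration error: target mean ", target_mean,
         " is not attainable below the eligibility ceiling ", upper,
         call. = FALSE)
  }
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(par) {
    m <- censored_normal_moments(par[1], exp(par[2]), upper)
    (m["mean"] - target_mean)^2 / max(target_mean, 1)^2 +
      (m["sd"] - target_sd)^2 / max(target_sd, 1)^2
  }
  starts <- list(c(target_mean, log(target_sd)),
                 c(-target_sd / 2, log(target_sd * 1.5)),
                 c(-target_sd, log(target_sd * 2)))
  best <- NULL
  for (s in starts) {
    fit <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (best$value > 1e-8) {
    stop("configuration error: no zero-censored normal matches mean ",
         target_mean, ", SD ", target_sd,
         if (is.finite(upper)) paste0(" under ceiling ", upper) else "",
         call. = FALSE)
  }
  c(mu = best$par[1], sigma = exp(best$par[2]))
}

default_timepoint_params <- function() {
  list(
    intervention = list(
      par = data.frame(week = c(0, 26, 52),
                       mean = c(8.0, 112.8, 108.6), sd = c(15.0, 97.1, 107.2)),
      accelerometer = data.frame(week = c(0, 26, 52),
                                 mean = c(35.8, 75.8, 70.4),
                                 sd = c(69.7, 91.0, 86.4))
    ),
    control = list(
      par = data.frame(week = c(0, 26, 52),
                       mean = c(8.5, 63.5, 75.9), sd = c(14.6, 88.7, 89.8)),
      accelerometer = data.frame(week = c(0, 26, 52),
                                 mean = c(28.7, 43.0, 55.5),
                                 sd = c(48.2, 60.9, 74.6))
    )
  )
}

default_staff_tasks <- function() {
  data.frame(
    task = c("orientation visit", "1-week call", "1-month call",
             "materials preparation", "9-month call", "resend and support",
             "staff training",
             "orientation visit", "materials preparation", "9-month call",
             "resend and support", "staff training"),
    arm = c(rep("intervention", 7), rep("control", 5)),
    category = c(rep("personnel_delivery", 6), "personnel_training",
                 rep("personnel_delivery", 4), "personnel_training"),
    phase = c(1, 1, 1, 1, 2, 2, 1, 1, 1, 2, 2, 1),
    per = c(rep("participant", 6), "cohort",
            rep("participant", 4), "cohort"),
    minutes = c(60, 15, 15, 16, 15, 30, 594, 30, 8, 15, 7, 198),
    rate_label = c(rep("research_associate", 6), "trainer",
                   rep("research_associate", 4), "trainer"),
    attempt_minutes = c(0, 5, 5, 0, 5, 0, 0, 5, 0, 5, 0, 0),
    attempts_lambda = 0,
    stringsAsFactors = FALSE
  )
}

#' Configuration for a synthetic two-arm activity trial
#'
#' Defines the generative model for [simulate_trial()]: per-arm, per-measure
#' weekly-MVPA distributions at each assessment week, the dropout fraction,
#' the within-person correlation, the baseline eligibility ceiling, and the
#' staff task catalog for [simulate_staff_log()]. Defaults emulate a two-arm
#' web-delivered physical-activity trial in underactive women: 104/101
#' participants, self-reported MVPA rising from about 8 to about 113 (63 in
#' control) weekly minutes by 6 months, 16.1\% dropout equal across arms.
#'
#' Weekly minutes are modelled as zero-censored Gaussians (a point mass of
#' fully inactive weeks plus a continuous part), with the latent location and
#' scale moment-matched so that the realised mean and SD equal the configured
#' ones — including the effect of the baseline eligibility ceiling.
#' Timepoints within a person are tied by a Gaussian copula with exchangeable
#' correlation `rho`.
#'
#' @param n_per_arm Named vector `c(intervention = , control = )`.
#' @param timepoints Nested list `$<arm>$<measure>` of
#'   `data.frame(week, mean, sd)`; defaults via the printed trial values.
#' @param dropout Non-completion fraction, equal across arms (`[0, 1)`).
#' @param rho Within-person correlation of the latent Gaussian across
#'   timepoints (exchangeable), default 0.4.
#' @param eligibility_max_baseline Screening ceiling on baseline self-reported
#'   weekly minutes (default 60; applies to the `par` measure).
#' @param staff_tasks Task catalog `data.frame(task, arm, category, phase,
#'   per, minutes, rate_label, attempt_minutes, attempts_lambda)`.
#' @return Object of class `trial_sim_config`.
#' @export
trial_sim_config <- function(n_per_arm = c(intervention = 104, control = 101),
                             timepoints = default_timepoint_params(),
                             dropout = 0.161,
                             rho = 0.4,
                             eligibility_max_baseline = 60,
                             staff_tasks = default_staff_tasks()) {
  if (any(n_per_arm <= 0)) stop("arm sizes must be > 0", call. = FALSE)
  if (dropout < 0 || dropout >= 1) {
    stop("`dropout` must be in [0, 1)", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)", call. = FALSE)
  for (arm in names(timepoints)) for (m in names(timepoints[[arm]])) {
    tp <- timepoints[[arm]][[m]]
    if (any(tp$sd < 0)) stop("SDs must be >= 0", call. = FALSE)
    if (is.unsorted(tp$week, strictly = TRUE)) {
      stop("timepoint weeks must be strictly increasing", call. = FALSE)
    }
  }
  structure(
    list(n_per_arm = n_per_arm, timepoints = timepoints, dropout = dropout,
         rho = rho, eligibility_max_baseline = eligibility_max_baseline,
         staff_tasks = staff_tasks),
    class = "trial_sim_config"
  )
}

# Draw n rows of latent exchangeable-correlation Gaussians with the first
# coordinate truncated above at cut (eligibility on the latent baseline).
draw_latent <- function(n, k, rho, cut = Inf) {
  z0 <- qnorm(runif(n) * pnorm(cut))
  if (k == 1) return(matrix(z0, ncol = 1))
  cond_var <- matrix(rho - rho^2, k - 1, k - 1)
  diag(cond_var) <- 1 - rho^2
  L <- chol(cond_var)
  eps <- matrix(rnorm(n * (k - 1)), n, k - 1) %*% L
  cbind(z0, sweep(eps, 1, rho * z0, "+"))
}

#' Simulate a synthetic two-arm activity trial
#'
#' Draws per-participant weekly-MVPA values at each assessment week for both
#' measures, applies the baseline eligibility rule, and marks a random
#' dropout fraction as non-completers (whose post-baseline values are `NA`).
#' Fully reproducible for a given `seed`.
#'
#' The latent means of post-baseline timepoints are shifted to compensate for
#' the eligibility conditioning (screening selects slightly less-active
#' people, and the within-person correlation would otherwise propagate that
#' selection to follow-up), so that realised completer means match the
#' configured ones.
#'
#' @param config A [trial_sim_config()].
#' @param seed Integer seed.
#' @return `data.frame` with one row per participant: `id`, `arm`,
#'   `completed`, and columns `<measure>_w<week>`.
#' @examples
#' rec <- simulate_trial(trial_sim_config(), seed = 1)
#' head(rec)
#' @export
simulate_trial <- function(config, seed = 1) {
  stopifnot(inherits(config, "trial_sim_config"))
  set.seed(seed)
  arms <- names(config$n_per_arm)
  out <- list()
  for (arm in arms) {
    n <- config$n_per_arm[[arm]]
    rec <- data.frame(id = paste0(substr(arm, 1, 1), seq_len(n)), arm = arm,
                      completed = rbinom(n, 1, 1 - config$dropout) == 1,
                      stringsAsFactors = FALSE)
    for (m in names(config$timepoints[[arm]])) {
      tp <- config$timepoints[[arm]][[m]]
      k <- nrow(tp)
      ceiling_m <- if (m == "par") config$eligibility_max_baseline else Inf
      pars <- matrix(NA_real_, k, 2, dimnames = list(NULL, c("mu", "sigma")))
      pars[1, ] <- censored_normal_params(tp$mean[1], tp$sd[1], ceiling_m)
      for (j in seq_len(k)[-1]) {
        pars[j, ] <- censored_normal_params(tp$mean[j], tp$sd[j], Inf)
      }
      cut <- if (is.finite(ceiling_m) && pars[1, "sigma"] > 0) {
        (ceiling_m - pars[1, "mu"]) / pars[1, "sigma"]
      } else Inf
      z <- draw_latent(n, k, config$rho, cut)
      # Compensate follow-up latents for the eligibility selection.
      shift <- if (is.finite(cut)) {
        config$rho * dnorm(cut) / pnorm(cut)
      } else 0
      vals <- matrix(NA_real_, n, k)
      for (j in seq_len(k)) {
        adj <- if (j == 1) 0 else shift * pars[j, "sigma"]
        vals[, j] <- pmax(0, pars[j, "mu"] + adj + pars[j, "sigma"] * z[, j])
      }
      vals[!rec$completed, -1] <- NA_real_
      colnames(vals) <- paste0(m, "_w", tp$week)
      rec <- cbind(rec, vals)
    }
    out[[arm]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize participant records into per-arm outcome series
#'
#' Completer-only means, SDs, and n at each assessment week, per arm and
#' measure — the inputs the effectiveness analysis expects.
#'
#' @param records Output of [simulate_trial()].
#' @return Named list of [outcome_series()] keyed `"<arm>.<measure>"`.
#' @export
summarize_to_series <- function(records) {
  val_cols <- grep("_w[0-9]+$", names(records), value = TRUE)
  measures <- unique(sub("_w[0-9]+$", "", val_cols))
  out <- list()
  for (arm in unique(records$arm)) {
    comp <- records[records$arm == arm & records$completed, ]
    if (nrow(comp) < 2) {
      stop("arm '", arm, "' has fewer than 2 completers", call. = FALSE)
    }
    for (m in measures) {
      cols <- val_cols[startsWith(val_cols, paste0(m, "_w"))]
      weeks <- as.numeric(sub(".*_w", "", cols))
      ord <- order(weeks)
      out[[paste(arm, m, sep = ".")]] <- outcome_series(
        arm, m, weeks[ord],
        vapply(cols[ord], function(cc) mean(comp[[cc]]), numeric(1)),
        vapply(cols[ord], function(cc) sd(comp[[cc]]), numeric(1)),
        rep(nrow(comp), length(cols))
      )
    }
  }
  out
}

#' Simulate a staff task-time log
#'
#' Emits one time entry per participant and per-participant task (phase-2
#' tasks only for participants still enrolled in the maintenance phase), plus
#' failed contact attempts drawn from a Poisson distribution where the task
#' catalog specifies them, and one per-cohort entry per cohort-level task
#' (e.g. staff training).
#'
#' @param config A [trial_sim_config()].
#' @param records Participant records from [simulate_trial()]; simulated with
#'   defaults when omitted.
#' @param seed Integer seed for the attempt draws.
#' @return `data.frame(arm, participant_id, task, category, phase, minutes,
#'   rate_label)`; cohort-level rows have `participant_id = NA`.
#' @export
simulate_staff_log <- function(config, records = NULL, seed = 1) {
  stopifnot(inherits(config, "trial_sim_config"))
  tasks <- config$staff_tasks
  if (is.null(tasks) || nrow(tasks) == 0) {
    return(data.frame(arm = character(), participant_id = character(),
                      task = character(), category = character(),
                      phase = numeric(), minutes = numeric(),
                      rate_label = character()))
  }
  if (is.null(records)) records <- simulate_trial(config, seed = seed)
  set.seed(seed + 1L)
  entries <- list()
  for (i in seq_len(nrow(tasks))) {
    tk <- tasks[i, ]
    if (tk$per == "cohort") {
      entries[[length(entries) + 1]] <- data.frame(
        arm = tk$arm, participant_id = NA_character_, task = tk$task,
        category = tk$category, phase = tk$phase, minutes = tk$minutes,
        rate_label = tk$rate_label, stringsAsFactors = FALSE)
      next
    }
    sub <- records[records$arm == tk$arm, ]
    if (tk$phase == 2) sub <- sub[sub$completed, ]
    if (nrow(sub) == 0) next
    attempts <- if (tk$attempts_lambda > 0) {
      rpois(nrow(sub), tk$attempts_lambda)
    } else rep(0L, nrow(sub))
    entries[[length(entries) + 1]] <- data.frame(
      arm = tk$arm, participant_id = sub$id, task = tk$task,
      category = tk$category, phase = tk$phase,
      minutes = tk$minutes + attempts * tk$attempt_minutes,
      rate_label = tk$rate_label, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, entries)
  rownames(res) <- NULL
  res
}

#' Cost a staff log at loaded personnel rates
#'
#' @param log Staff log from [simulate_staff_log()].
#' @param rates Rate table from [read_personnel_rates()] (or
#'   [pasos_personnel_rates()]); must cover every `rate_label` in the log.
#' @return `data.frame(arm, category, phase, cost)` with per-entry costs
#'   rounded to cents and summed.
#' @export
staff_log_cost <- function(log, rates) {
  if (nrow(log) == 0) {
    return(data.frame(arm = character(), category = character(),
                      phase = numeric(), cost = numeric()))
  }
  j <- match(log$rate_label, rates$label)
  if (anyNA(j)) {
    stop("unknown rate label '", log$rate_label[which(is.na(j))[1]], "'",
         call. = FALSE)
  }
  log$cost <- vapply(seq_len(nrow(log)),
                     function(i) personnel_cost(log$minutes[i] / 60,
                                                rates$hourly_loaded[j[i]]),
                     numeric(1))
  agg <- aggregate(cost ~ arm + category + phase, data = log, FUN = sum)
  agg[order(agg$arm, agg$category, agg$phase), ]
}
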