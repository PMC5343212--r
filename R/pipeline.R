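#' Read and validate an analysis configuration
#'
#' Configuration may be YAML (`.yaml`/`.yml`) or JSON. Recognized fields:
#' `ledger_csv` (required), `outcomes_csv` (required), `rates_csv`
#' (optional, for basis-level ledgers), `n_intervention`, `n_control`,
#' `horizons`, `sensitivity_delta`, `scaling` (list with `arm`,
#' `horizon_months`, `n_from`, `n_to`, `n_by`), `gain_overrides` and
#' `cost_overrides` (inline records or a CSV path), and `seed`. Relative
#' paths are resolved against the config file's directory.
#'
#' @param path Config file path, or a ready-made list (validated in place).
#' @return Validated config list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (is.list(path)) {
    cfg <- path
    base <- "."
  } else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    }
    base <- dirname(path)
  }
  resolve <- function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  }
  for (f in c("ledger_csv", "outcomes_csv", "rates_csv")) {
    cfg[[f]] <- resolve(cfg[[f]])
  }
  for (f in c("ledger_csv", "outcomes_csv")) {
    if (is.null(cfg[[f]])) {
      stop("configuration error: `", f, "` is required", call. = FALSE)
    }
    if (!file.exists(cfg[[f]])) {
      stop("configuration error: `", f, "` file not found: ", cfg[[f]],
           call. = FALSE)
    }
  }
  defaults <- list(n_intervention = 104, n_control = 101,
                   horizons = c(6, 12), sensitivity_delta = 0.2,
                   scaling = list(arm = "intervention", horizon_months = 12,
                                  n_from = 25, n_to = 1000, n_by = 25),
                   seed = 1)
  for (f in names(defaults)) if (is.null(cfg[[f]])) cfg[[f]] <- defaults[[f]]
  if (cfg$sensitivity_delta <= -1) {
    stop("configuration error: sensitivity delta must exceed -1", call. = FALSE)
  }
  for (f in c("gain_overrides", "cost_overrides")) {
    ov <- cfg[[f]]
    if (is.character(ov) && length(ov) == 1) {
      ov <- resolve(ov)
      if (!file.exists(ov)) {
        stop("configuration error: `", f, "` file not found: ", ov,
             call. = FALSE)
      }
      cfg[[f]] <- read.csv(ov, stringsAsFactors = FALSE)
    } else if (is.list(ov) && !is.data.frame(ov)) {
      cfg[[f]] <- do.call(rbind, lapply(ov, as.data.frame))
    }
  }
  structure(cfg, class = c("analysis_config", "list"))
}

md_table <- function(df, digits = 2) {
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, format = "f", digits = digits,
                               drop0trailing = TRUE) else as.character(v)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  lines <- c(
    paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  )
  paste(lines, collapse = "\n")
}

#' Run the full costing and cost-effectiveness pipeline
#'
#' Orchestrates every analysis stage from input files to report files:
#' reads the ledger and outcome series, writes the per-arm cost summary, the
#' cost-effectiveness table (CSV, JSON keyed by measure/horizon/statistic,
#' and Markdown), the one-way sensitivity table, the enrollment-scaling
#' curve, and a run log (package and R versions, seed, config echo). Outputs
#' are plain text and byte-identical across runs with identical inputs.
#'
#' @param config Path to a YAML/JSON config, or a config list
#'   (see [read_analysis_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results: `ledger`,
#'   `cost_summary`, `cea`, `sensitivity`, `curve_points`, and the paths
#'   written.
#' @examples
#' cfg <- list(ledger_csv = system.file("extdata", "pasos_costs.csv",
#'                                      package = "activecost"),
#'             outcomes_csv = system.file("extdata", "pasos_outcomes.csv",
#'                                        package = "activecost"))
#' res <- run_pipeline(cfg, out_dir = tempfile("report"))
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_analysis_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rates <- if (!is.null(cfg$rates_csv)) read_personnel_rates(cfg$rates_csv)
  ledger <- read_cost_ledger(cfg$ledger_csv, rates = rates,
                             n_intervention = cfg$n_intervention,
                             n_control = cfg$n_control)
  outcomes <- read_outcome_series(cfg$outcomes_csv)

  cost_summary <- summary(ledger)
  fit <- cost_effectiveness(ledger, outcomes, horizons = cfg$horizons,
                            gain_overrides = cfg$gain_overrides,
                            cost_overrides = cfg$cost_overrides)
  sens <- sensitivity_table(ledger, outcomes, delta = cfg$sensitivity_delta,
                            horizons = cfg$horizons,
                            gain_overrides = cfg$gain_overrides,
                            cost_overrides = cfg$cost_overrides)
  curve <- scaling_curve(ledger, cfg$scaling$arm, cfg$scaling$horizon_months)
  grid <- seq(cfg$scaling$n_from, cfg$scaling$n_to, by = cfg$scaling$n_by)
  curve_points <- predict(curve, grid)

  paths <- list(
    cost_summary = file.path(out_dir, "cost_summary.csv"),
    ce_table = file.path(out_dir, "ce_table.csv"),
    ce_report = file.path(out_dir, "ce_report.json"),
    ce_markdown = file.path(out_dir, "ce_table.md"),
    sensitivity = file.path(out_dir, "sensitivity.csv"),
    scaling = file.path(out_dir, "scaling_curve.csv"),
    run_log = file.path(out_dir, "run_log.json")
  )
  write.csv(cost_summary, paths$cost_summary, row.names = FALSE)
  write.csv(fit$table, paths$ce_table, row.names = FALSE)
  write.csv(as.data.frame(sens), paths$sensitivity, row.names = FALSE)
  write.csv(curve_points, paths$scaling, row.names = FALSE)

  # JSON report: every table cell keyed (measure, horizon, statistic);
  # dollar totals reported whole, ratios in cents.
  report <- list()
  for (i in seq_len(nrow(fit$table))) {
    key <- paste0(fit$table$measure[i], "_", fit$table$horizon_months[i], "mo")
    row <- fit$table[i, ]
    report[[key]] <- list(
      gain_intervention = row$gain_intervention,
      gain_control = row$gain_control,
      gain_per_month_intervention = row$gain_per_month_intervention,
      gain_per_month_control = row$gain_per_month_control,
      cost_per_minute_intervention = row$cost_per_minute_intervention,
      cost_per_minute_control = row$cost_per_minute_control,
      incremental_cost_per_minute = row$incremental_cost_per_minute,
      tolerance_note = "arm totals reproduce itemized columns within $2"
    )
  }
  jsonlite::write_json(report, paths$ce_report, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  md <- paste0(
    "## Cost-effectiveness of MVPA gain\n\n", md_table(fit$table),
    "\n\n## One-way sensitivity (incremental cost per minute)\n\n",
    md_table(as.data.frame(sens)[
      c("scenario", "multiplier", "measure", "horizon_months",
        "incremental_cost_per_minute")]),
    "\n"
  )
  writeLines(md, paths$ce_markdown)

  run_log <- list(
    package = "activecost",
    package_version = as.character(packageVersion("activecost")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = unclass(cfg)[!vapply(unclass(cfg), is.data.frame, logical(1))],
    inputs = list(
      ledger_md5 = unname(tools::md5sum(cfg$ledger_csv)),
      outcomes_md5 = unname(tools::md5sum(cfg$outcomes_csv))
    )
  )
  jsonlite::write_json(run_log, paths$run_log, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(ledger = ledger, cost_summary = cost_summary, cea = fit,
                 sensitivity = sens, curve = curve,
                 curve_points = curve_points, paths = paths))
}
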