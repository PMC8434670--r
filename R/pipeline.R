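# End-to-end commands tying the modules together: simulate, process, report.
# These back the command-line front-end in inst/cli/silogrowth.R; exit codes
# there follow the returned status (0 ok, 2 input error, 3 alerts fired).

log_msg <- function(stage, ..., level = "INFO") {
  message(sprintf("%s [%s] %s: %s", fmt_utc(Sys.time()), level, stage,
                  paste0(...)))
}

#' Simulate a scenario and write its files
#'
#' @param scenario a [scenario_config()] or path to a scenario YAML/JSON.
#' @param outdir output directory; receives `readings.csv`, `batch.yaml`,
#'   `truth.json`.
#' @param seed optional seed overriding the scenario's.
#' @return the `silo_scenario`, invisibly.
#' @export
run_simulate <- function(scenario, outdir, seed = NULL) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  sc <- simulate_scenario(scenario)
  write_scenario(sc, outdir)
  n_ref <- if (is.null(sc$truth$trace$refill_log)) 0 else
    nrow(sc$truth$trace$refill_log)
  log_msg("simulate", sprintf(
    "batch %s: %d weeks, %d animals, %d refills -> %s",
    sc$batch$batch_id, scenario$horizon_weeks,
    sum(sc$batch$entries$n_animals), n_ref, outdir))
  invisible(sc)
}

#' Process a level series and batch records through the full pipeline
#'
#' Runs refill detection, density estimation, cleaning, consumption, weekly
#' intake, growth distribution and alert evaluation, and writes
#' `cleaned_weight.csv`, `weekly_intake.csv`, `distribution.csv`,
#' `alerts.json` and `summary.json` to `outdir`.
#'
#' @param readings path to `readings.csv`/`.json`, or a [level_series()].
#' @param batch path to `batch.yaml`/`.json`, or a [batch_config()].
#' @param outdir output directory.
#' @param cleaning a [cleaning_config()].
#' @param rules an [alert_rules()].
#' @param dist_week week for the reported weight distribution (default: last
#'   complete week).
#' @param notifier optional notifier for [dispatch_alerts()]; `NULL` skips
#'   dispatch.
#' @return invisibly, a list with all intermediate results plus `status`
#'   (0 = ok, 3 = alerts fired).
#' @export
run_process <- function(readings, batch, outdir,
                        cleaning = cleaning_config(), rules = alert_rules(),
                        dist_week = NULL, notifier = NULL) {
  if (is.character(readings)) readings <- read_level_series(readings)
  if (is.character(batch)) batch <- read_batch_config(batch)
  stopifnot(inherits(readings, "level_series"),
            inherits(batch, "batch_config"))

  res <- process_silo(readings, batch, cleaning)
  log_msg("silo", sprintf("%d readings, %d refills detected, %d segments",
                          nrow(readings), nrow(res$refills),
                          nrow(res$densities)))
  intake <- intake_series(res$consumption, batch)
  if (is.null(dist_week)) dist_week <- max(intake$week)
  comps <- subgroup_distributions(intake, batch, dist_week)
  dist <- merge_and_bin(comps)
  dev <- deviation_series(intake)
  alerts <- evaluate_alerts(dev, refill_weeks(res$refills, batch$start_date),
                            rules, res$missing_by_week)
  delivery <- if (!is.null(notifier)) dispatch_alerts(alerts, notifier)

  summary <- list(
    batch_id = batch$batch_id,
    weeks = nrow(intake),
    n_animals_entered = sum(batch$entries$n_animals),
    n_animals_present = unname(animals_present(
      batch, batch$start_date + 7 * nrow(intake) - 1)),
    total_consumption_kg = sum(res$consumption$daily$consumed_kg),
    afi_sensor_final_kg = intake$afi_sensor_kg[nrow(intake)],
    afi_theory_final_kg = intake$afi_theory_kg[nrow(intake)],
    distribution_week = dist_week,
    distribution_tail_below_zero = dist$tail_below_zero,
    n_alerts = nrow(alerts))

  out <- list(series = readings, batch = batch, silo = res, intake = intake,
              distribution = dist, deviation = dev, alerts = alerts,
              delivery = delivery, summary = summary,
              status = if (nrow(alerts) > 0) 3L else 0L)
  write_outputs(list(cleaned = data.frame(
    timestamp = res$cleaned$timestamp,
    weight_kg = res$cleaned$weight_kg),
    intake = intake, distribution = dist,
    alerts = alerts, summary = summary), outdir)
  log_msg("process", sprintf("wrote outputs to %s (%d alerts)", outdir,
                             nrow(alerts)))
  invisible(out)
}

#' Print a human-readable summary of processed outputs
#'
#' @param outdir directory previously written by [run_process()].
#' @return invisibly, a list with the tables read back.
#' @export
run_report <- function(outdir) {
  paths <- file.path(outdir, c("weekly_intake.csv", "distribution.csv",
                               "alerts.json", "summary.json"))
  if (!all(file.exists(paths))) {
    stop("processed outputs not found under ", outdir)
  }
  intake <- utils::read.csv(paths[1])
  dist <- utils::read.csv(paths[2])
  alerts <- jsonlite::fromJSON(paths[3])
  summary <- jsonlite::fromJSON(paths[4])

  cat(sprintf("Batch %s - %d weeks, %d animals entered, %d present\n",
              summary$batch_id, summary$weeks, summary$n_animals_entered,
              summary$n_animals_present))
  cat(sprintf("Total feed consumed: %.0f kg\n", summary$total_consumption_kg))
  cat("\nWeekly accumulated feed intake (kg/animal):\n")
  print(data.frame(week = intake$week,
                   sensor = round(intake$afi_sensor_kg, 2),
                   theory = round(intake$afi_theory_kg, 2),
                   deviation = round(intake$deviation, 4)),
        row.names = FALSE)
  cat(sprintf("\nExpected weight distribution (week %d, %g kg bins):\n",
              summary$distribution_week,
              dist$bin_high_kg[1] - dist$bin_low_kg[1]))
  show <- dist[dist$expected_count >= 0.5, , drop = FALSE]
  print(data.frame(range_kg = sprintf("[%g, %g)", show$bin_low_kg,
                                      show$bin_high_kg),
                   animals = round(show$expected_count, 1)),
        row.names = FALSE)
  if (length(alerts) == 0 || NROW(alerts) == 0) {
    cat("\nNo alerts.\n")
  } else {
    cat("\nAlerts:\n")
    for (i in seq_len(NROW(alerts))) {
      cat(sprintf("  [%s] week %d: %s\n", alerts$kind[i], alerts$week[i],
                  alerts$message[i]))
    }
  }
  invisible(list(intake = intake, distribution = dist, alerts = alerts,
                 summary = summary))
}
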