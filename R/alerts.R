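# Deviation and data-quality alerting with a pluggable notifier contract.

#' Alert rule configuration
#'
#' @param deviation_threshold relative deviation (fraction) beyond which a
#'   week counts as deviating; default 0.10.
#' @param consecutive_weeks number of consecutive deviating weeks required
#'   before a growth alert fires; default 2.
#' @param data_check_first when `TRUE` (default), a deviation span containing
#'   a refill without a declared weight raises a data-verification alert
#'   instead of a growth alert: data accuracy is checked before the animals
#'   are blamed.
#' @param missing_fraction_threshold share of a week's readings that may be
#'   missing before a missing-data alert fires; default 0.25.
#' @return object of class `alert_rules`.
#' @export
alert_rules <- function(deviation_threshold = 0.10, consecutive_weeks = 2,
                        data_check_first = TRUE,
                        missing_fraction_threshold = 0.25) {
  if (deviation_threshold <= 0) stop("deviation_threshold must be > 0")
  if (consecutive_weeks < 1) stop("consecutive_weeks must be >= 1")
  structure(list(deviation_threshold = deviation_threshold,
                 consecutive_weeks = as.integer(consecutive_weeks),
                 data_check_first = isTRUE(data_check_first),
                 missing_fraction_threshold = missing_fraction_threshold),
            class = "alert_rules")
}

new_alert <- function(kind, week, magnitude, message) {
  data.frame(kind = kind, week = as.integer(week),
             magnitude = as.numeric(magnitude), message = message,
             stringsAsFactors = FALSE)
}

#' Evaluate alert rules on a deviation series
#'
#' Emits one `growth_deviation` alert at the first week of every maximal run
#' of at least `consecutive_weeks` weeks whose absolute deviation exceeds the
#' threshold. If `data_check_first` is set and any refill inside the
#' deviating span lacks a declared weight, a `verify_refill_data` alert is
#' emitted for that span instead of (never in addition to) the growth alert.
#' A `missing_data` alert is emitted for every week whose missing-reading
#' fraction exceeds the configured share.
#'
#' @param deviation data.frame with columns `week`, `deviation` (see
#'   [deviation_series()]).
#' @param refills optional refill table with columns `week` and
#'   `declared_weight` (`NA` = not declared); see [refill_weeks()].
#' @param rule an [alert_rules()].
#' @param missing_by_week optional data.frame with `week`,
#'   `missing_fraction`.
#' @return data.frame with columns `kind`, `week`, `magnitude`, `message`
#'   (zero rows when nothing fires). Deterministic and idempotent.
#' @export
evaluate_alerts <- function(deviation, refills = NULL, rule = alert_rules(),
                            missing_by_week = NULL) {
  if (is.null(deviation) || nrow(deviation) == 0) {
    stop("deviation series is empty")
  }
  alerts <- new_alert(character(), integer(), numeric(), character())

  over <- abs(deviation$deviation) > rule$deviation_threshold
  over[is.na(over)] <- FALSE
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (g in which(r$values & r$lengths >= rule$consecutive_weeks)) {
    span <- deviation$week[starts[g]:ends[g]]
    mag <- max(abs(deviation$deviation[starts[g]:ends[g]]))
    undeclared <- if (!is.null(refills) && nrow(refills)) {
      refills$week[is.na(refills$declared_weight) & refills$week %in% span]
    } else integer(0)
    if (rule$data_check_first && length(undeclared)) {
      alerts <- rbind(alerts, new_alert(
        "verify_refill_data", min(undeclared), mag,
        sprintf(paste0("Intake deviates %.1f%% over weeks %d-%d but the ",
                       "refill in week %d has no declared weight; verify ",
                       "the refill data before reviewing the animals."),
                100 * mag, min(span), max(span), min(undeclared))))
    } else {
      alerts <- rbind(alerts, new_alert(
        "growth_deviation", min(span), mag,
        sprintf(paste0("Sensor-based intake deviates from the theoretical ",
                       "curve by up to %.1f%% for %d consecutive weeks ",
                       "starting week %d."),
                100 * mag, length(span), min(span))))
    }
  }

  if (!is.null(missing_by_week) && nrow(missing_by_week)) {
    for (i in which(missing_by_week$missing_fraction >
                      rule$missing_fraction_threshold)) {
      alerts <- rbind(alerts, new_alert(
        "missing_data", missing_by_week$week[i],
        missing_by_week$missing_fraction[i],
        sprintf("%.0f%% of the readings in week %d are missing.",
                100 * missing_by_week$missing_fraction[i],
                missing_by_week$week[i])))
    }
  }
  alerts[order(alerts$week), , drop = FALSE]
}

#' Week index of each refill relative to the batch start
#'
#' @param refills a [refill_events()]-like data.frame with `timestamp` and
#'   `declared_weight`.
#' @param start_date batch start date.
#' @return data.frame with `week`, `declared_weight`.
#' @export
refill_weeks <- function(refills, start_date) {
  if (is.null(refills) || nrow(refills) == 0) {
    return(data.frame(week = integer(), declared_weight = numeric()))
  }
  data.frame(week = week_of_day(day_index(refills$timestamp, start_date)),
             declared_weight = refills$declared_weight)
}

#' Default notifier: write alerts to the structured log
#'
#' A notifier is any function taking one message string; it must error on
#' delivery failure. The default appends a timestamped record to a
#' connection.
#'
#' @param con connection (default `stderr()`).
#' @return a notifier function.
#' @export
log_notifier <- function(con = stderr()) {
  function(message) {
    writeLines(sprintf("%s ALERT %s", fmt_utc(Sys.time()), message), con)
    invisible(TRUE)
  }
}

#' Dispatch alerts through a notifier
#'
#' Each alert is delivered exactly once; a notifier failure is recorded and
#' processing continues with the remaining alerts.
#'
#' @param alerts data.frame from [evaluate_alerts()].
#' @param notifier a function `(message) -> anything`, erroring on failure.
#' @return data.frame with one row per alert: `kind`, `week`, `delivered`,
#'   `error` (empty string when delivered).
#' @export
dispatch_alerts <- function(alerts, notifier = log_notifier()) {
  if (is.null(alerts) || nrow(alerts) == 0) {
    return(data.frame(kind = character(), week = integer(),
                      delivered = logical(), error = character(),
                      stringsAsFactors = FALSE))
  }
  report <- lapply(seq_len(nrow(alerts)), function(i) {
    res <- tryCatch({
      notifier(alerts$message[i])
      list(TRUE, "")
    }, error = function(e) list(FALSE, conditionMessage(e)))
    data.frame(kind = alerts$kind[i], week = alerts$week[i],
               delivered = res[[1]], error = res[[2]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, report)
}
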