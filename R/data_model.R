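# Domain types and file readers/writers.
#
# All timestamps are POSIXct in UTC; farmer-entered dates are Date and are
# interpreted as midnight UTC. Week index t = floor(days since batch start/7),
# 0-based, half-open weeks [7t, 7t+7).

SECONDS_PER_DAY <- 86400

#' Parse ISO-8601 timestamps as UTC
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS`, the space-separated variant, an optional
#' trailing `Z`, and bare dates (taken as midnight UTC).
#'
#' @param x character vector.
#' @return POSIXct vector in UTC; unparseable elements become `NA`.
#' @keywords internal
parse_utc <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  y <- sub("Z$", "", x)
  y <- sub("T", " ", y, fixed = TRUE)
  out <- as.POSIXct(y, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  miss <- is.na(out) & !is.na(y)
  if (any(miss)) {
    out[miss] <- as.POSIXct(y[miss], tz = "UTC", format = "%Y-%m-%d")
  }
  out
}

#' @keywords internal
fmt_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Day index of a timestamp relative to a batch start date
#' @keywords internal
day_index <- function(t, start_date) {
  t0 <- as.POSIXct(paste0(format(start_date, "%Y-%m-%d"), " 00:00:00"),
                   tz = "UTC")
  floor(as.numeric(difftime(t, t0, units = "days")))
}

#' Week index (0-based) of a day index
#' @keywords internal
week_of_day <- function(day) as.integer(floor(day / 7))

# ---------------------------------------------------------------------------
# Level series

#' Construct a level series
#'
#' A level series holds timestamped silo fill-fraction readings, nominally one
#' every two hours. Fill fraction is the occupied share of the usable silo
#' volume, in `[0, 1]`. Readings whose value could not be measured or parsed
#' carry `quality = "missing"` and an `NA` fraction.
#'
#' @param timestamp POSIXct (UTC), strictly increasing.
#' @param level_fraction numeric in `[0, 1]`, `NA` allowed for missing rows.
#' @param quality `"ok"` or `"missing"`; defaults to `"missing"` where
#'   `level_fraction` is `NA`.
#' @param nominal_interval expected spacing between readings, seconds
#'   (default 7200 = 2 h).
#' @return data.frame of class `level_series` with columns `timestamp`,
#'   `level_fraction`, `quality` and attribute `nominal_interval`.
#' @export
level_series <- function(timestamp, level_fraction,
                         quality = NULL, nominal_interval = 7200) {
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  level_fraction <- as.numeric(level_fraction)
  if (length(timestamp) != length(level_fraction)) {
    stop("timestamp and level_fraction must have equal length")
  }
  if (is.null(quality)) {
    quality <- ifelse(is.na(level_fraction), "missing", "ok")
  }
  quality <- match.arg(quality, c("ok", "missing"), several.ok = TRUE)
  quality[is.na(level_fraction)] <- "missing"
  if (anyNA(timestamp)) stop("unparseable timestamp in level series")
  if (anyDuplicated(timestamp)) {
    dup <- timestamp[duplicated(timestamp)][1]
    stop("duplicate timestamp in level series: ", fmt_utc(dup))
  }
  ord <- order(timestamp)
  ok <- quality == "ok"
  bad <- ok & (level_fraction < 0 | level_fraction > 1)
  if (any(bad, na.rm = TRUE)) {
    stop("level_fraction outside [0, 1] at ",
         fmt_utc(timestamp[which(bad)[1]]))
  }
  out <- data.frame(timestamp = timestamp[ord],
                    level_fraction = level_fraction[ord],
                    quality = quality[ord],
                    stringsAsFactors = FALSE)
  attr(out, "nominal_interval") <- nominal_interval
  class(out) <- c("level_series", "data.frame")
  out
}

#' Read a level series from CSV or JSON
#'
#' The CSV must have a header with columns `timestamp` and `level_fraction`;
#' the JSON alternative is an array of objects with the same keys. Rows whose
#' level cell is empty or unparseable are kept and flagged `missing`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @param nominal_interval expected reading spacing in seconds.
#' @return a [level_series()].
#' @export
read_level_series <- function(path, format = c("auto", "csv", "json"),
                              nominal_interval = 7200) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("readings file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  need <- c("timestamp", "level_fraction")
  if (!all(need %in% names(df))) {
    stop("readings file must have columns timestamp, level_fraction")
  }
  ts <- parse_utc(df$timestamp)
  if (anyNA(ts)) {
    stop("unparseable timestamp in ", path, " at row ", which(is.na(ts))[1])
  }
  lv <- suppressWarnings(as.numeric(df$level_fraction))
  level_series(ts, lv, nominal_interval = nominal_interval)
}

#' Write a level series to CSV
#' @param series a [level_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_level_series <- function(series, path) {
  df <- data.frame(timestamp = fmt_utc(series$timestamp),
                   level_fraction = ifelse(is.na(series$level_fraction), "",
                                           format_num(series$level_fraction)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Silo geometry

#' Silo geometry specification
#'
#' Maps fill fraction to occupied volume. `linear` treats volume as
#' proportional to the fill fraction. `cylinder_cone` models the usual feed
#' silo: an inverted cone of height `cone_height` under a cylindrical body of
#' height `body_height`, both of the given `diameter`; the fill fraction then
#' refers to fill height over total height and the feed occupies the cone
#' first.
#'
#' @param usable_volume total usable volume, m^3.
#' @param geometry `"linear"` or `"cylinder_cone"`.
#' @param body_height,cone_height,diameter metres; required for
#'   `cylinder_cone`, where the implied total volume must agree with
#'   `usable_volume` within 0.1%.
#' @return object of class `silo_spec`.
#' @export
silo_spec <- function(usable_volume, geometry = c("linear", "cylinder_cone"),
                      body_height = NULL, cone_height = NULL, diameter = NULL) {
  geometry <- match.arg(geometry)
  if (!is.numeric(usable_volume) || usable_volume <= 0) {
    stop("usable_volume must be > 0")
  }
  spec <- list(usable_volume = as.numeric(usable_volume), geometry = geometry,
               body_height = body_height, cone_height = cone_height,
               diameter = diameter)
  if (geometry == "cylinder_cone") {
    if (is.null(body_height) || is.null(cone_height) || is.null(diameter)) {
      stop("cylinder_cone geometry needs body_height, cone_height, diameter")
    }
    r <- diameter / 2
    vtot <- pi * r^2 * (cone_height / 3 + body_height)
    if (abs(vtot - usable_volume) > 1e-3 * usable_volume) {
      stop(sprintf(paste0("cylinder_cone volume %.4f m^3 disagrees with ",
                          "usable_volume %.4f m^3 by more than 0.1%%"),
                   vtot, usable_volume))
    }
  }
  class(spec) <- "silo_spec"
  spec
}

# ---------------------------------------------------------------------------
# Density

#' Feed density state
#'
#' Feed density differs between truckloads, so the pipeline keeps one density
#' per silo segment (a segment is the span between two refills). Until a
#' refill's declared weight allows re-estimation, the default applies.
#'
#' @param default_density kg/m^3, > 0.
#' @param segment_densities optional data.frame with columns `segment`,
#'   `density`.
#' @return object of class `density_state`.
#' @export
density_state <- function(default_density, segment_densities = NULL) {
  if (!is.numeric(default_density) || default_density <= 0) {
    stop("default_density must be > 0")
  }
  if (!is.null(segment_densities)) {
    segment_densities <- as.data.frame(segment_densities)
    if (any(segment_densities$density <= 0)) {
      stop("all segment densities must be > 0")
    }
  }
  structure(list(default_density = as.numeric(default_density),
                 segment_densities = segment_densities),
            class = "density_state")
}

#' Refill events
#'
#' @param timestamp POSIXct (UTC) of each refill.
#' @param declared_weight declared load weight in kg; `NA` when the farmer has
#'   not entered it.
#' @param detected_volume_delta detected volume jump in m^3 (may be `NA` for
#'   farmer-declared refills not yet matched to the sensor trace).
#' @return data.frame of class `refill_events`.
#' @export
refill_events <- function(timestamp = as.POSIXct(character(), tz = "UTC"),
                          declared_weight = numeric(),
                          detected_volume_delta = numeric()) {
  n <- length(timestamp)
  declared_weight <- rep_len(as.numeric(declared_weight), n)
  detected_volume_delta <- if (length(detected_volume_delta)) {
    rep_len(as.numeric(detected_volume_delta), n)
  } else {
    rep(NA_real_, n)
  }
  if (any(!is.na(declared_weight) & declared_weight <= 0)) {
    stop("declared_weight must be > 0 when present")
  }
  if (any(!is.na(detected_volume_delta) & detected_volume_delta <= 0)) {
    stop("detected_volume_delta must be > 0")
  }
  out <- data.frame(timestamp = as.POSIXct(timestamp, tz = "UTC"),
                    declared_weight = declared_weight,
                    detected_volume_delta = detected_volume_delta)
  class(out) <- c("refill_events", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Growth parameters

#' Growth-model parameters
#'
#' Parameters of the two curves driving the analytics: the logistic
#' accumulated-feed-intake curve `AFI(age) = A_feed / (1 + exp(-b_feed * age))`
#' (age in weeks) and the Gompertz body-weight curve
#' `AW = A_weight * exp(-exp(b_weight - k_weight * AFI))`, plus a cubic
#' polynomial giving the weight variance (kg^2) as a function of weeks since a
#' subgroup's entry, and the conventional technical parameters ADG (average
#' daily gain, kg/day) and FCR (feed conversion rate, kg feed per kg gain)
#' used for a secondary linear intake cross-check.
#'
#' @param A_feed asymptotic adult accumulated feed intake, kg.
#' @param b_feed logistic rate, 1/weeks.
#' @param A_weight asymptotic adult body weight, kg.
#' @param b_weight Gompertz offset (dimensionless).
#' @param k_weight Gompertz rate, 1/kg of accumulated feed.
#' @param var_coeffs numeric length 4, `(c0, c1, c2, c3)`; variance at week t
#'   is `c0 + c1 t + c2 t^2 + c3 t^3` and must stay > 0 over
#'   `0..horizon_weeks`.
#' @param adg,fcr technical parameters; optional (`NA`) if the linear
#'   cross-check is not wanted.
#' @param horizon_weeks horizon over which the variance polynomial is
#'   validated (default 25).
#' @return object of class `growth_params`.
#' @export
growth_params <- function(A_feed, b_feed, A_weight, b_weight, k_weight,
                          var_coeffs, adg = NA_real_, fcr = NA_real_,
                          horizon_weeks = 25) {
  stopifnot(length(var_coeffs) == 4)
  if (A_feed <= 0 || b_feed <= 0 || A_weight <= 0 || k_weight <= 0) {
    stop("A_feed, b_feed, A_weight and k_weight must be > 0")
  }
  wk <- 0:horizon_weeks
  v <- var_coeffs[1] + var_coeffs[2] * wk + var_coeffs[3] * wk^2 +
    var_coeffs[4] * wk^3
  if (any(v <= 0)) {
    stop("variance polynomial is not positive at week ", wk[which(v <= 0)[1]])
  }
  structure(list(A_feed = A_feed, b_feed = b_feed, A_weight = A_weight,
                 b_weight = b_weight, k_weight = k_weight,
                 var_coeffs = as.numeric(var_coeffs),
                 adg = as.numeric(adg), fcr = as.numeric(fcr),
                 horizon_weeks = as.integer(horizon_weeks)),
            class = "growth_params")
}

# ---------------------------------------------------------------------------
# Batch configuration

#' Batch configuration
#'
#' A fattening batch is defined by its earliest entrance of animals; it may
#' contain several entry subgroups (one per truck of piglets), departures to
#' the abattoir over the marketing window, the silo refill log, and the
#' growth-model, density and silo-geometry parameters.
#'
#' @param batch_id character identifier.
#' @param entries data.frame with columns `entry_date` (Date), `n_animals`,
#'   `avg_weight` (kg), `age_weeks` (age at entry).
#' @param departures data.frame with columns `date` (Date), `n_removed`,
#'   `abattoir_weight` (kg, total for the group); may be empty/NULL.
#' @param refills a [refill_events()] data.frame; may be empty/NULL.
#' @param growth a [growth_params()].
#' @param density a [density_state()].
#' @param silo a [silo_spec()].
#' @return object of class `batch_config`. The batch start date is the
#'   earliest entry date. Cumulative departures may never exceed cumulative
#'   entries on any date.
#' @export
batch_config <- function(batch_id, entries, departures = NULL, refills = NULL,
                         growth, density, silo) {
  entries <- as.data.frame(entries)
  need <- c("entry_date", "n_animals", "avg_weight", "age_weeks")
  if (!all(need %in% names(entries)) || nrow(entries) == 0) {
    stop("entries needs >= 1 row with columns ", paste(need, collapse = ", "))
  }
  entries$entry_date <- as.Date(entries$entry_date)
  if (any(entries$n_animals < 1)) stop("each entry needs n_animals >= 1")
  if (any(entries$avg_weight <= 0)) stop("each entry needs avg_weight > 0")
  entries <- entries[order(entries$entry_date), , drop = FALSE]
  rownames(entries) <- NULL

  if (is.null(departures)) {
    departures <- data.frame(date = as.Date(character()),
                             n_removed = integer(),
                             abattoir_weight = numeric())
  }
  departures <- as.data.frame(departures)
  if (nrow(departures)) {
    departures$date <- as.Date(departures$date)
    if (any(departures$n_removed < 1)) stop("n_removed must be >= 1")
    departures <- departures[order(departures$date), , drop = FALSE]
    rownames(departures) <- NULL
  }
  if (is.null(refills)) refills <- refill_events()

  stopifnot(inherits(growth, "growth_params"),
            inherits(density, "density_state"),
            inherits(silo, "silo_spec"))

  cfg <- structure(list(batch_id = as.character(batch_id), entries = entries,
                        departures = departures, refills = refills,
                        growth = growth, density = density, silo = silo,
                        start_date = min(entries$entry_date)),
                   class = "batch_config")
  # invariant: departures never outrun entries on any date
  dates <- sort(unique(c(entries$entry_date, departures$date)))
  for (d in seq_along(dates)) {
    ne <- sum(entries$n_animals[entries$entry_date <= dates[d]])
    nd <- if (nrow(departures)) {
      sum(departures$n_removed[departures$date <= dates[d]])
    } else 0
    if (nd > ne) {
      stop("cumulative departures exceed cumulative entries on ",
           format(dates[d]))
    }
  }
  cfg
}

#' Number of animals present on a given day
#'
#' Entries and departures take effect at the start of their day (inclusive),
#' so the count is a right-continuous step function of the date.
#'
#' @param config a [batch_config()].
#' @param day a Date (or day index relative to batch start).
#' @return integer count, never negative.
#' @export
animals_present <- function(config, day) {
  stopifnot(inherits(config, "batch_config"))
  if (is.numeric(day)) day <- config$start_date + day
  day <- as.Date(day)
  if (any(day < config$start_date)) {
    stop("day precedes batch start (", format(config$start_date), ")")
  }
  vapply(day, function(d) {
    ne <- sum(config$entries$n_animals[config$entries$entry_date <= d])
    nd <- if (nrow(config$departures)) {
      sum(config$departures$n_removed[config$departures$date <= d])
    } else 0
    as.integer(ne - nd)
  }, integer(1))
}

# ---------------------------------------------------------------------------
# Batch config file IO (YAML / JSON)

config_to_list <- function(config) {
  refills <- config$refills
  list(
    batch_id = config$batch_id,
    entries = lapply(seq_len(nrow(config$entries)), function(i) {
      e <- config$entries[i, ]
      list(entry_date = format(e$entry_date), n_animals = e$n_animals,
           avg_weight = e$avg_weight, age_weeks = e$age_weeks)
    }),
    departures = lapply(seq_len(nrow(config$departures)), function(i) {
      d <- config$departures[i, ]
      list(date = format(d$date), n_removed = d$n_removed,
           abattoir_weight = d$abattoir_weight)
    }),
    refills = lapply(seq_len(nrow(refills)), function(i) {
      r <- refills[i, ]
      out <- list(timestamp = fmt_utc(r$timestamp))
      if (!is.na(r$declared_weight)) out$declared_weight <- r$declared_weight
      out
    }),
    growth = list(A_feed = config$growth$A_feed, b_feed = config$growth$b_feed,
                  A_weight = config$growth$A_weight,
                  b_weight = config$growth$b_weight,
                  k_weight = config$growth$k_weight,
                  var_coeffs = config$growth$var_coeffs,
                  adg = config$growth$adg, fcr = config$growth$fcr,
                  horizon_weeks = config$growth$horizon_weeks),
    density = list(default_density = config$density$default_density),
    silo = list(usable_volume = config$silo$usable_volume,
                geometry = config$silo$geometry,
                body_height = config$silo$body_height,
                cone_height = config$silo$cone_height,
                diameter = config$silo$diameter)
  )
}

list_to_config <- function(x) {
  entries <- do.call(rbind, lapply(x$entries, function(e) {
    data.frame(entry_date = as.Date(e$entry_date),
               n_animals = as.integer(e$n_animals),
               avg_weight = as.numeric(e$avg_weight),
               age_weeks = as.numeric(e$age_weeks))
  }))
  departures <- if (length(x$departures)) {
    do.call(rbind, lapply(x$departures, function(d) {
      data.frame(date = as.Date(d$date), n_removed = as.integer(d$n_removed),
                 abattoir_weight = as.numeric(d$abattoir_weight))
    }))
  } else NULL
  refills <- if (length(x$refills)) {
    refill_events(
      timestamp = parse_utc(vapply(x$refills, `[[`, "", "timestamp")),
      declared_weight = vapply(x$refills, function(r) {
        if (is.null(r$declared_weight)) NA_real_ else as.numeric(r$declared_weight)
      }, numeric(1)))
  } else NULL
  g <- x$growth
  adg <- if (is.null(g$adg)) NA_real_ else as.numeric(g$adg)
  fcr <- if (is.null(g$fcr)) NA_real_ else as.numeric(g$fcr)
  hz <- if (is.null(g$horizon_weeks)) 25 else as.integer(g$horizon_weeks)
  growth <- growth_params(g$A_feed, g$b_feed, g$A_weight, g$b_weight,
                          g$k_weight, unlist(g$var_coeffs), adg, fcr, hz)
  s <- x$silo
  silo <- silo_spec(s$usable_volume,
                    if (is.null(s$geometry)) "linear" else s$geometry,
                    s$body_height, s$cone_height, s$diameter)
  batch_config(x$batch_id, entries, departures, refills, growth,
               density_state(x$density$default_density), silo)
}

#' Read a batch configuration from YAML or JSON
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return a [batch_config()].
#' @export
read_batch_config <- function(path) {
  if (!file.exists(path)) stop("batch config file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  list_to_config(x)
}

#' Write a batch configuration to YAML or JSON
#' @param config a [batch_config()].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_batch_config <- function(config, path) {
  x <- config_to_list(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Result writers

format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 15, scientific = FALSE, trim = TRUE)
  }, character(1))
}

#' Write pipeline outputs to a directory
#'
#' Writes `cleaned_weight.csv` (timestamp, weight_kg), `weekly_intake.csv`
#' (week, afi_sensor_kg, afi_theory_kg, afi_linear_kg, deviation),
#' `distribution.csv` (bin_low_kg, bin_high_kg, expected_count),
#' `alerts.json` and `summary.json`. Numbers are written with enough digits
#' that re-reading reproduces integers exactly and floats to 1e-9 relative.
#'
#' @param results list with elements `cleaned` (data.frame timestamp,
#'   weight_kg), `intake` (weekly intake data.frame), `distribution` (a
#'   weight distribution, see [merge_and_bin()]), `alerts` (data.frame),
#'   `summary` (list).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_outputs <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)

  cw <- results$cleaned
  utils::write.csv(data.frame(timestamp = fmt_utc(cw$timestamp),
                              weight_kg = format_num(cw$weight_kg)),
                   file.path(dir, "cleaned_weight.csv"),
                   row.names = FALSE, quote = FALSE)

  wi <- results$intake
  utils::write.csv(data.frame(week = wi$week,
                              afi_sensor_kg = format_num(wi$afi_sensor_kg),
                              afi_theory_kg = format_num(wi$afi_theory_kg),
                              afi_linear_kg = format_num(wi$afi_linear_kg),
                              deviation = format_num(wi$deviation)),
                   file.path(dir, "weekly_intake.csv"),
                   row.names = FALSE, quote = FALSE)

  bins <- if (is.null(results$distribution)) {
    data.frame(bin_low_kg = numeric(), bin_high_kg = numeric(),
               expected_count = numeric())
  } else {
    results$distribution$bins
  }
  utils::write.csv(data.frame(bin_low_kg = format_num(bins$bin_low_kg),
                              bin_high_kg = format_num(bins$bin_high_kg),
                              expected_count = format_num(bins$expected_count)),
                   file.path(dir, "distribution.csv"),
                   row.names = FALSE, quote = FALSE)

  alerts <- results$alerts
  if (is.null(alerts)) {
    alerts <- data.frame(kind = character(), week = integer(),
                         magnitude = numeric(), message = character())
  }
  jsonlite::write_json(alerts, file.path(dir, "alerts.json"),
                       auto_unbox = FALSE, digits = NA, dataframe = "rows")

  jsonlite::write_json(results$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
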