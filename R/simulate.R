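# Digital twin of a fattening batch fed from a sensor-monitored silo:
# generates ground-truthed intake, growth, refill and level-reading data so
# every pipeline stage can be tested without hardware.

#' Scenario configuration for the batch/silo simulator
#'
#' Defaults emulate the monitored farms: a batch of 600 pigs entering at 10
#' weeks of age and fattened for 18 weeks from a 20 m^3 silo (12,800 kg at
#' the default 640 kg/m^3 density), read every 2 hours with occasional
#' missing readings, refilled with 6,000 kg truckloads whenever the level
#' falls to 20%, each load drawing its own density.
#'
#' @param seed integer seed; one pseudo-random stream per scenario, consumed
#'   in documented order (per-load densities during the silo pass, then the
#'   reading-noise vector, then the missingness vector).
#' @param n_animals head count of the first entry (500-900 typical).
#' @param horizon_weeks length of the fattening period (17-20 typical).
#' @param entry_age_weeks age at entry, weeks.
#' @param start_date batch start date (first entry).
#' @param entries optional data.frame `entry_week`, `n_animals`, `age_weeks`
#'   for multi-entry batches; overrides `n_animals`/`entry_age_weeks`.
#' @param silo a [silo_spec()].
#' @param true_density_default density of the feed initially in the silo,
#'   kg/m^3; also used as the pipeline's default density.
#' @param density_range per-truckload density range (uniform draw), kg/m^3.
#' @param initial_fill initial fill fraction of the silo.
#' @param reorder_level fill fraction that triggers a refill order.
#' @param load_size_kg truckload size, kg.
#' @param noise_sd sd of additive Gaussian reading noise, as a fraction of
#'   capacity (level units).
#' @param missing_prob probability that a reading is missing, < 0.5.
#' @param growth true [growth_params()] driving intake and weight.
#' @param anomalies optional data.frame `start_week`, `multiplier`: intake is
#'   scaled by `multiplier` from `start_week` on (until a later row takes
#'   over).
#' @param constant_intake_kg_day if set, replaces the logistic intake model
#'   with a constant per-animal daily intake (useful for exactness tests).
#' @param marketing_weight target slaughter weight, kg; departures start when
#'   the subgroup average weight crosses it.
#' @param marketing_window_weeks maximum number of weekly departures.
#' @param truckload animals removed per departure.
#' @param withhold_refills indices of refills whose declared weight is
#'   withheld from the batch records.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L, n_animals = 600L, horizon_weeks = 18L,
                            entry_age_weeks = 10, start_date = as.Date("2021-03-01"),
                            entries = NULL,
                            silo = silo_spec(20),
                            true_density_default = 640,
                            density_range = c(600, 680),
                            initial_fill = 0.9,
                            reorder_level = 0.2,
                            load_size_kg = 6000,
                            noise_sd = 0.01,
                            missing_prob = 0.05,
                            growth = growth_params(A_feed = 1100,
                                                   b_feed = 0.065,
                                                   A_weight = 230,
                                                   b_weight = 0.7115,
                                                   k_weight = 0.00481,
                                                   var_coeffs = c(9, 2, 0.35, 0),
                                                   adg = 0.8, fcr = 2.6),
                            anomalies = NULL,
                            constant_intake_kg_day = NULL,
                            marketing_weight = 110,
                            marketing_window_weeks = 5,
                            truckload = 100,
                            withhold_refills = integer(0)) {
  if (missing_prob < 0 || missing_prob >= 0.5) {
    stop("missing_prob must be in [0, 0.5)")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(entries)) {
    entries <- data.frame(entry_week = 0L, n_animals = as.integer(n_animals),
                          age_weeks = entry_age_weeks)
  }
  structure(list(seed = as.integer(seed), horizon_weeks = as.integer(horizon_weeks),
                 start_date = as.Date(start_date), entries = entries,
                 silo = silo, true_density_default = true_density_default,
                 density_range = density_range, initial_fill = initial_fill,
                 reorder_level = reorder_level, load_size_kg = load_size_kg,
                 noise_sd = noise_sd, missing_prob = missing_prob,
                 growth = growth, anomalies = anomalies,
                 constant_intake_kg_day = constant_intake_kg_day,
                 marketing_weight = marketing_weight,
                 marketing_window_weeks = as.integer(marketing_window_weeks),
                 truckload = as.integer(truckload),
                 withhold_refills = as.integer(withhold_refills)),
            class = "scenario_config")
}

anomaly_multiplier <- function(cfg, week) {
  mult <- rep(1, length(week))
  a <- cfg$anomalies
  if (!is.null(a) && nrow(a)) {
    a <- a[order(a$start_week), , drop = FALSE]
    for (i in seq_len(nrow(a))) {
      mult[week >= a$start_week[i]] <- a$multiplier[i]
    }
  }
  mult
}

#' Simulate the animal side of a scenario
#'
#' Per-animal daily intake is the day-differenced logistic AFI curve at each
#' subgroup's age, scaled by any injected anomaly multiplier; subgroup
#' average weights come from the Gompertz curve on the (anomaly-affected)
#' cumulative intake. Departures are scheduled deterministically: from the
#' week the first subgroup's average weight crosses the marketing weight,
#' one truckload leaves per week over the marketing window (while more than
#' a truckload remains).
#'
#' This step draws no random numbers; all randomness lives in
#' [simulate_silo_trace()].
#'
#' @param cfg a [scenario_config()].
#' @return list with `truth` (daily intake per subgroup, daily batch
#'   consumption, weekly true AFI and AW, head counts) and `batch` (a
#'   [batch_config()] without refills yet).
#' @export
simulate_batch <- function(cfg) {
  H <- cfg$horizon_weeks
  n_days <- 7L * H
  dvec <- 0:(n_days - 1L)
  g <- function(age) cfg$growth$A_feed / (1 + exp(-cfg$growth$b_feed * age))
  ne <- nrow(cfg$entries)
  entry_day <- 7L * cfg$entries$entry_week
  mult_day <- anomaly_multiplier(cfg, week_of_day(dvec))

  # per-animal daily intake per subgroup (kg), 0 before entry
  intake <- matrix(0, nrow = ne, ncol = n_days)
  for (i in seq_len(ne)) {
    on_farm <- dvec >= entry_day[i]
    a0 <- cfg$entries$age_weeks[i] + (dvec - entry_day[i]) / 7
    base <- if (is.null(cfg$constant_intake_kg_day)) {
      g(a0 + 1 / 7) - g(a0)
    } else {
      rep(cfg$constant_intake_kg_day, n_days)
    }
    intake[i, ] <- ifelse(on_farm, base * mult_day, 0)
  }
  cum_intake <- t(apply(intake, 1, cumsum))
  if (ne == 1) cum_intake <- matrix(cumsum(intake[1, ]), nrow = 1)

  # weekly true subgroup AW (Gompertz on anomaly-affected cumulative intake)
  wk <- 0:(H - 1L)
  aw <- matrix(NA_real_, nrow = ne, ncol = H)
  for (i in seq_len(ne)) {
    for (t in wk) {
      if (t >= cfg$entries$entry_week[i]) {
        aw[i, t + 1L] <- gompertz_weight(cum_intake[i, 7 * (t + 1)],
                                         cfg$growth)
      }
    }
  }

  # departure schedule from the first subgroup's crossing week
  entry_w <- gompertz_weight(0, cfg$growth)
  departures <- NULL
  cross <- which(aw[1, ] >= cfg$marketing_weight)
  if (length(cross)) {
    w0 <- wk[cross[1]]
    remaining <- sum(cfg$entries$n_animals)
    dep_weeks <- seq(w0, min(w0 + cfg$marketing_window_weeks - 1L, H - 1L))
    rows <- list()
    for (w in dep_weeks) {
      if (remaining <= cfg$truckload) break
      rows[[length(rows) + 1L]] <- data.frame(
        date = cfg$start_date + 7L * w,
        n_removed = cfg$truckload,
        abattoir_weight = cfg$truckload * aw[1, w + 1L])
      remaining <- remaining - cfg$truckload
    }
    if (length(rows)) departures <- do.call(rbind, rows)
  }

  entries_df <- data.frame(entry_date = cfg$start_date + entry_day,
                           n_animals = cfg$entries$n_animals,
                           avg_weight = entry_w,
                           age_weeks = cfg$entries$age_weeks)
  batch <- batch_config(sprintf("sim-%04d", cfg$seed), entries_df, departures,
                        NULL, cfg$growth,
                        density_state(cfg$true_density_default), cfg$silo)

  heads <- vapply(dvec, function(d) subgroup_headcounts(batch, d),
                  numeric(ne))
  heads <- matrix(heads, nrow = ne)
  daily_batch <- colSums(heads * intake)
  n_present <- vapply(dvec, function(d) animals_present(batch, d), integer(1))
  per_animal_day <- ifelse(n_present > 0, daily_batch / n_present, 0)
  afi_true <- vapply(wk, function(t) sum(per_animal_day[seq_len(7 * (t + 1))]),
                     numeric(1))

  truth <- list(daily_intake_per_subgroup = intake,
                cum_intake_per_subgroup = cum_intake,
                daily_batch_consumption = daily_batch,
                n_present_day = n_present,
                week = wk,
                afi_true = afi_true,
                aw_true = aw,
                total_consumption = sum(daily_batch))
  list(truth = truth, batch = batch)
}

#' Simulate the silo level trace for a batch
#'
#' The silo starts at `initial_fill` with feed at the default density; mass
#' declines linearly within each day at the batch's true consumption rate.
#' A reading is taken every 2 hours; when a reading finds the fill fraction
#' at or below the reorder level, a truckload lands one hour later, its
#' density drawn uniformly from `density_range`, and the contents blend
#' mass-weighted. Gaussian noise (sd = `noise_sd` of capacity) is added to
#' each level reading and readings are dropped to `missing` with
#' `missing_prob`.
#'
#' @param sim result of [simulate_batch()].
#' @param cfg the same [scenario_config()].
#' @return list with `series` (a [level_series()]), `refills` (declared
#'   refill events for the batch records, declared weights withheld where
#'   configured) and `truth_trace` (exact masses, volumes, per-segment
#'   densities and the full refill log).
#' @export
simulate_silo_trace <- function(sim, cfg) {
  batch <- sim$batch
  truth <- sim$truth
  H <- cfg$horizon_weeks
  n_days <- 7L * H
  V <- cfg$silo$usable_volume
  D <- truth$daily_batch_consumption

  cumD <- c(0, cumsum(D))
  consumed_at <- function(tsec) {                # cumulative kg consumed by tsec
    d <- floor(tsec / SECONDS_PER_DAY)
    d <- pmin(pmax(d, 0), n_days - 1L)
    full <- cumD[d + 1L]
    full + D[d + 1L] * (tsec - d * SECONDS_PER_DAY) / SECONDS_PER_DAY
  }

  t0 <- as.POSIXct(paste(format(cfg$start_date), "00:00:00"), tz = "UTC")
  n_read <- 12L * n_days + 1L
  tsec <- (seq_len(n_read) - 1L) * 7200
  timestamps <- t0 + tsec

  m0 <- cfg$initial_fill * V * cfg$true_density_default
  rho <- cfg$true_density_default
  loads_mass <- 0
  level_exact <- numeric(n_read)
  mass_exact <- numeric(n_read)
  seg <- integer(n_read)
  seg_id <- 1L
  refill_log <- list()

  # feed trucks deliver during working hours: the first reading-interval
  # midpoint (odd hour) between 09:00 and 17:00 after the reorder trigger
  next_delivery <- function(tsec_now) {
    d <- floor(tsec_now / SECONDS_PER_DAY)
    cand <- c(outer(c(9, 11, 13, 15, 17) * 3600, (d + 0:1) * SECONDS_PER_DAY,
                    `+`))
    min(cand[cand > tsec_now])
  }

  pending <- NA_real_
  for (k in seq_len(n_read)) {
    if (!is.na(pending) && pending < tsec[k]) {
      m_pre <- m0 + loads_mass - consumed_at(pending)
      rho_load <- stats::runif(1, cfg$density_range[1], cfg$density_range[2])
      v_load <- cfg$load_size_kg / rho_load
      if (m_pre / rho + v_load > V) {
        stop("infeasible refill policy: load exceeds silo capacity")
      }
      rho_new <- blend_density(m_pre, rho, cfg$load_size_kg, rho_load)
      refill_log[[length(refill_log) + 1L]] <- data.frame(
        timestamp = t0 + pending, load_mass = cfg$load_size_kg,
        load_density = rho_load, mass_pre = m_pre,
        density_after = rho_new, segment = seg_id + 1L)
      loads_mass <- loads_mass + cfg$load_size_kg
      rho <- rho_new
      seg_id <- seg_id + 1L
      pending <- NA_real_
    }
    m <- m0 + loads_mass - consumed_at(tsec[k])
    if (m < 0) stop("infeasible refill policy: silo ran empty on day ",
                    floor(tsec[k] / SECONDS_PER_DAY))
    mass_exact[k] <- m
    seg[k] <- seg_id
    level_exact[k] <- (m / rho) / V
    if (is.na(pending) && level_exact[k] <= cfg$reorder_level &&
          k < n_read) {
      pending <- next_delivery(tsec[k])
    }
  }

  noise <- stats::rnorm(n_read, 0, cfg$noise_sd)
  miss <- stats::runif(n_read) < cfg$missing_prob
  lv <- pmin(pmax(level_exact + noise, 0), 1)
  lv[miss] <- NA_real_

  series <- level_series(timestamps, lv)
  log_df <- if (length(refill_log)) do.call(rbind, refill_log) else NULL
  declared <- if (!is.null(log_df)) {
    dw <- log_df$load_mass
    if (length(cfg$withhold_refills)) {
      dw[intersect(cfg$withhold_refills, seq_along(dw))] <- NA_real_
    }
    refill_events(timestamp = log_df$timestamp, declared_weight = dw)
  } else {
    refill_events()
  }
  list(series = series, refills = declared,
       truth_trace = list(mass_exact = mass_exact,
                          level_exact = level_exact,
                          segment = seg,
                          initial_mass = m0,
                          refill_log = log_df))
}

#' Simulate a complete scenario
#'
#' Seeds the stream, runs [simulate_batch()] and [simulate_silo_trace()],
#' and assembles the final [batch_config()] including the declared refills.
#'
#' @param cfg a [scenario_config()].
#' @return list of class `silo_scenario` with `series`, `batch`, `truth`
#'   (animal-side ground truth plus the `trace` element) and `config`.
#' @export
simulate_scenario <- function(cfg) {
  set.seed(cfg$seed)
  sim <- simulate_batch(cfg)
  tr <- simulate_silo_trace(sim, cfg)
  batch <- batch_config(sim$batch$batch_id, sim$batch$entries,
                        if (nrow(sim$batch$departures)) sim$batch$departures,
                        tr$refills, cfg$growth,
                        density_state(cfg$true_density_default), cfg$silo)
  truth <- sim$truth
  truth$trace <- tr$truth_trace
  structure(list(series = tr$series, batch = batch, truth = truth,
                 config = cfg),
            class = "silo_scenario")
}

#' Write simulator outputs to a directory
#'
#' Writes the same `readings.csv` and `batch.yaml` formats the pipeline
#' reads, plus `truth.json` with the ground truth for tests.
#'
#' @param scenario a `silo_scenario` from [simulate_scenario()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_level_series(scenario$series, file.path(dir, "readings.csv"))
  write_batch_config(scenario$batch, file.path(dir, "batch.yaml"))
  truth <- scenario$truth
  tj <- list(week = truth$week,
             afi_true = truth$afi_true,
             aw_true = truth$aw_true,
             daily_batch_consumption = truth$daily_batch_consumption,
             n_present_day = truth$n_present_day,
             total_consumption = truth$total_consumption,
             initial_mass = truth$trace$initial_mass,
             refill_log = truth$trace$refill_log)
  if (!is.null(tj$refill_log)) {
    tj$refill_log$timestamp <- fmt_utc(tj$refill_log$timestamp)
  }
  jsonlite::write_json(tj, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE, dataframe = "columns",
                       matrix = "rowmajor", null = "null")
  invisible(dir)
}

#' Read a scenario configuration from YAML or JSON
#'
#' Keys mirror the arguments of [scenario_config()]; `silo`, `growth`,
#' `anomalies` and `entries` are nested maps.
#'
#' @param path file path.
#' @return a [scenario_config()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- x
  if (!is.null(x$silo)) {
    s <- x$silo
    args$silo <- silo_spec(s$usable_volume,
                           if (is.null(s$geometry)) "linear" else s$geometry,
                           s$body_height, s$cone_height, s$diameter)
  }
  if (!is.null(x$growth)) {
    g <- x$growth
    args$growth <- growth_params(g$A_feed, g$b_feed, g$A_weight, g$b_weight,
                                 g$k_weight, unlist(g$var_coeffs),
                                 if (is.null(g$adg)) NA_real_ else g$adg,
                                 if (is.null(g$fcr)) NA_real_ else g$fcr)
  }
  if (!is.null(x$anomalies)) {
    args$anomalies <- do.call(rbind, lapply(x$anomalies, as.data.frame))
  }
  if (!is.null(x$entries)) {
    args$entries <- do.call(rbind, lapply(x$entries, as.data.frame))
  }
  if (!is.null(x$density_range)) args$density_range <- unlist(x$density_range)
  if (!is.null(x$withhold_refills)) {
    args$withhold_refills <- unlist(x$withhold_refills)
  }
  if (!is.null(x$start_date)) args$start_date <- as.Date(x$start_date)
  do.call(scenario_config, args)
}
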