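# Raw level readings -> cleaned feed-weight series -> per-interval and daily
# consumption. Segments are the spans between refills; smoothing never
# crosses a refill.

#' Cleaning configuration
#'
#' @param window odd number of readings for the centered moving average;
#'   default 13 (about one day at the 2-hour cadence).
#' @param refill_threshold minimum cumulative volume jump (m^3) for an
#'   increase run to count as a refill; default 1.
#' @param max_gap_interpolate longest run of consecutive missing readings
#'   still filled by linear interpolation; default 6 (12 h). Consumption over
#'   longer gaps is assigned to the day the gap ends.
#' @return object of class `cleaning_config`.
#' @export
cleaning_config <- function(window = 13, refill_threshold = 1,
                            max_gap_interpolate = 6) {
  window <- as.integer(window)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  if (refill_threshold <= 0) stop("refill_threshold must be > 0")
  structure(list(window = window, refill_threshold = refill_threshold,
                 max_gap_interpolate = as.integer(max_gap_interpolate)),
            class = "cleaning_config")
}

#' Convert fill fraction to occupied volume
#'
#' For `linear` geometry the volume is `fraction * usable_volume`. For
#' `cylinder_cone` the fraction refers to fill height over total height; the
#' feed fills the inverted cone first (volume growing with the cube of the
#' fill height), then the cylindrical body.
#'
#' @param level_fraction numeric in `[0, 1]` (vectorised).
#' @param silo a [silo_spec()].
#' @return occupied volume, m^3.
#' @export
level_to_volume <- function(level_fraction, silo) {
  stopifnot(inherits(silo, "silo_spec"))
  x <- as.numeric(level_fraction)
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) stop("level_fraction outside [0, 1]")
  if (silo$geometry == "linear") {
    return(x * silo$usable_volume)
  }
  r <- silo$diameter / 2
  hc <- silo$cone_height
  hb <- silo$body_height
  H <- hc + hb
  h <- x * H
  v <- ifelse(h <= hc,
              pi * r^2 * h^3 / (3 * hc^2),
              pi * r^2 * hc / 3 + pi * r^2 * (h - hc))
  v
}

#' Convert occupied volume to feed weight
#' @param volume m^3, >= 0.
#' @param density kg/m^3, > 0.
#' @return weight in kg.
#' @export
volume_to_weight <- function(volume, density) {
  if (any(!is.na(density) & density <= 0)) stop("density must be > 0")
  if (any(!is.na(volume) & volume < 0)) stop("volume must be >= 0")
  volume * density
}

#' Centered moving average with symmetric edge truncation
#' @keywords internal
centered_ma <- function(y, window) {
  n <- length(y)
  hw <- (window - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(y[i])) next
    h <- min(hw, i - 1L, n - i)
    out[i] <- mean(y[(i - h):(i + h)], na.rm = TRUE)
  }
  out
}

#' Antitonic (non-increasing) projection via pool-adjacent-violators
#'
#' Wraps [stats::isoreg()] on the negated sequence.
#' @keywords internal
pav_antitonic <- function(y) {
  if (length(y) < 2) return(y)
  -stats::isoreg(seq_along(y), -y)$yf
}

# ---------------------------------------------------------------------------
# Refill detection

#' Detect refill events as increase runs in a level series
#'
#' A refill shows as an upward jump of the level. Every maximal run of
#' consecutive increases of the occupied volume whose cumulative gain reaches
#' `refill_threshold` becomes one event; the event timestamp is the first
#' reading of the run (the trough) and `detected_volume_delta` is the
#' cumulative gain over the run. Smaller increases are left to the smoother
#' as noise. Missing readings are skipped.
#'
#' Note the orchestrator ([process_silo()]) runs this detector on a
#' moving-average-smoothed copy of the series so that reading noise cannot
#' fake an increase run, then locates the raw jump inside each run.
#'
#' @param series a [level_series()].
#' @param silo a [silo_spec()].
#' @param cfg a [cleaning_config()].
#' @return a [refill_events()] data.frame with attribute `runs`: a data.frame
#'   of `start_row`/`end_row` indices (into `series`) bracketing each run.
#' @export
detect_refills <- function(series, silo, cfg = cleaning_config()) {
  stopifnot(inherits(series, "level_series"))
  ok <- which(series$quality == "ok")
  v <- level_to_volume(series$level_fraction[ok], silo)
  n <- length(v)
  ts <- integer(0); delta <- numeric(0)
  start_row <- integer(0); end_row <- integer(0)
  if (n >= 2) {
    i <- 1L
    while (i < n) {
      if (v[i + 1L] > v[i]) {
        j <- i
        while (j < n && v[j + 1L] > v[j]) j <- j + 1L
        gain <- v[j] - v[i]
        if (gain >= cfg$refill_threshold) {
          ts <- c(ts, ok[i]); delta <- c(delta, gain)
          start_row <- c(start_row, ok[i]); end_row <- c(end_row, ok[j])
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  ev <- refill_events(timestamp = series$timestamp[ts],
                      declared_weight = rep(NA_real_, length(ts)),
                      detected_volume_delta = delta)
  attr(ev, "runs") <- data.frame(start_row = start_row, end_row = end_row)
  ev
}

#' Estimate the density of a refill load
#'
#' With a declared load weight the density is `declared_weight /
#' detected_volume_delta`; without one the default density is used.
#'
#' @param event one-row [refill_events()] slice (or a list with
#'   `declared_weight` and `detected_volume_delta`).
#' @param density a [density_state()].
#' @return load density in kg/m^3.
#' @export
estimate_density <- function(event, density) {
  stopifnot(inherits(density, "density_state"))
  dw <- event$declared_weight
  dv <- event$detected_volume_delta
  if (!is.na(dw)) {
    if (is.na(dv) || dv <= 0) {
      stop("cannot calibrate density: declared weight present but no ",
           "positive detected volume delta")
    }
    return(dw / dv)
  }
  density$default_density
}

#' Mass-weighted density blend after a refill
#'
#' The feed remaining in the silo and the new load mix; the post-refill
#' segment density is their mass-weighted mean.
#'
#' @param mass_remaining,density_remaining contents before the refill.
#' @param mass_load,density_load the new truckload.
#' @return blended density, kg/m^3.
#' @export
blend_density <- function(mass_remaining, density_remaining,
                          mass_load, density_load) {
  m <- mass_remaining + mass_load
  if (m <= 0) stop("no mass to blend")
  (mass_remaining * density_remaining + mass_load * density_load) / m
}

# Piecewise-linear least squares with knots at UTC midnights; the level
# series is approximately linear within a day (consumption rate changes day
# by day), so this local model recovers the pre/post-refill volume exactly on
# noise-free traces and averages noise over a ~2-day window otherwise.
pwl_predict <- function(t, v, t_pred) {
  keep <- !is.na(v)
  t <- t[keep]; v <- v[keep]
  if (length(v) == 0) return(NA_real_)
  if (length(v) == 1) return(v)
  knots <- seq(ceiling(min(t) / SECONDS_PER_DAY),
               floor(max(t) / SECONDS_PER_DAY)) * SECONDS_PER_DAY
  knots <- knots[knots > min(t) & knots < max(t)]
  t0 <- min(t)
  Xl <- cbind(1, (t - t0) / SECONDS_PER_DAY)
  X <- Xl
  for (k in knots) X <- cbind(X, pmax((t - k) / SECONDS_PER_DAY, 0))
  n <- length(v)
  ql <- qr(Xl)
  bl <- qr.coef(ql, v)
  rss_lin <- sum(qr.resid(ql, v)^2)
  use_pw <- FALSE
  if (length(knots) && n > ncol(X)) {
    qp <- qr(X)
    bp <- qr.coef(qp, v)
    bp[is.na(bp)] <- 0
    rss_pw <- sum(qr.resid(qp, v)^2)
    df2 <- n - qp$rank
    q1 <- qp$rank - 2L
    # drain-rate kinks at midnights are kept only when they explain clearly
    # more than noise; a plain line has much lower prediction variance
    if (df2 > 0 && q1 > 0) {
      if (rss_pw <= 1e-16 * max(rss_lin, 1e-300)) {
        use_pw <- TRUE
      } else {
        f <- ((rss_lin - rss_pw) / q1) / (rss_pw / df2)
        use_pw <- is.finite(f) && f > stats::qf(0.99, q1, df2)
      }
    }
  }
  if (use_pw) {
    xp <- c(1, (t_pred - t0) / SECONDS_PER_DAY,
            pmax((t_pred - knots) / SECONDS_PER_DAY, 0))
    sum(xp * bp)
  } else {
    sum(c(1, (t_pred - t0) / SECONDS_PER_DAY) * bl)
  }
}

# Locate the raw jump step inside a detected run and refine the volume jump
# and pre-refill volume by local piecewise-linear regression on the raw
# volumes (window_days on each side, clipped to neighbouring jumps).
refine_refill <- function(tnum, vols, vols_filled, run_lo, run_hi, prev_hi,
                          next_lo, window_days = 3) {
  lo <- max(run_lo, prev_hi)
  hi <- min(run_hi, next_lo)
  steps <- diff(vols_filled[lo:hi])
  j <- lo + which.max(steps) - 1L        # jump between rows j and j+1
  tmid <- (tnum[j] + tnum[j + 1L]) / 2
  pre_keep <- which(tnum >= tnum[j] - window_days * SECONDS_PER_DAY &
                      tnum <= tnum[j] & seq_along(tnum) > prev_hi &
                      seq_along(tnum) <= j)
  post_keep <- which(tnum >= tnum[j + 1L] &
                       tnum <= tnum[j + 1L] + window_days * SECONDS_PER_DAY &
                       seq_along(tnum) >= j + 1L & seq_along(tnum) < next_lo)
  v_pre <- pwl_predict(tnum[pre_keep], vols[pre_keep], tmid)
  v_post <- pwl_predict(tnum[post_keep], vols[post_keep], tmid)
  v_left <- pwl_predict(tnum[pre_keep], vols[pre_keep], tnum[j])
  v_right <- pwl_predict(tnum[post_keep], vols[post_keep], tnum[j + 1L])
  if (is.na(v_pre)) v_pre <- vols[j]
  if (is.na(v_post)) v_post <- vols[j + 1L]
  if (is.na(v_left)) v_left <- vols[j]
  if (is.na(v_right)) v_right <- vols[j + 1L]
  list(jump_left = j, jump_right = j + 1L,
       volume_pre = v_pre, delta_refined = max(v_post - v_pre, 0),
       volume_left = v_left, volume_right = v_right)
}

#' Match farmer-declared refills to detected events
#'
#' Each detected event takes the declared weight of the nearest unmatched
#' declared refill within `tolerance` seconds.
#'
#' @param detected a [refill_events()] from detection.
#' @param declared a [refill_events()] from the batch configuration.
#' @param tolerance matching window in seconds (default 36 h).
#' @return `detected` with `declared_weight` filled where matched.
#' @export
match_refills <- function(detected, declared, tolerance = 36 * 3600) {
  if (is.null(declared) || nrow(declared) == 0 || nrow(detected) == 0) {
    return(detected)
  }
  used <- rep(FALSE, nrow(declared))
  for (i in seq_len(nrow(detected))) {
    dt <- abs(as.numeric(detected$timestamp[i]) -
                as.numeric(declared$timestamp))
    dt[used | is.na(declared$declared_weight)] <- Inf
    k <- which.min(dt)
    if (length(k) && dt[k] <= tolerance) {
      detected$declared_weight[i] <- declared$declared_weight[k]
      used[k] <- TRUE
    }
  }
  detected
}

# ---------------------------------------------------------------------------
# Cleaning

#' Clean a segmented weight series
#'
#' Within each segment independently (never smoothing across a refill):
#' gaps of up to `max_gap_interpolate` missing readings are filled by linear
#' interpolation on time; a centered moving average of width `window` is
#' applied, truncated symmetrically at segment edges; and monotonicity is
#' enforced by projecting onto the non-increasing cone with the
#' pool-adjacent-violators algorithm. Segments with fewer than two readings
#' pass through unchanged with a warning.
#'
#' @param wseries data.frame with columns `timestamp`, `weight_kg`,
#'   `segment` (class `weight_series`, as built by [process_silo()]).
#' @param cfg a [cleaning_config()].
#' @return the input with `weight_kg` replaced by the cleaned values.
#' @export
clean_series <- function(wseries, cfg = cleaning_config()) {
  out <- wseries
  for (s in unique(wseries$segment)) {
    idx <- which(wseries$segment == s)
    w <- wseries$weight_kg[idx]
    tn <- as.numeric(wseries$timestamp[idx])
    n_ok <- sum(!is.na(w))
    if (length(idx) < 2 || n_ok < 2) {
      warning("segment ", s, " has fewer than 2 readings; passed through")
      next
    }
    # 1. interpolate short internal gaps
    nas <- is.na(w)
    if (any(nas)) {
      r <- rle(nas)
      pos <- cumsum(c(1L, r$lengths))
      for (g in which(r$values)) {
        a <- pos[g]; b <- pos[g + 1L] - 1L
        internal <- a > 1L && b < length(w)
        if (internal && r$lengths[g] <= cfg$max_gap_interpolate) {
          w[a:b] <- stats::approx(tn[c(a - 1L, b + 1L)],
                                  w[c(a - 1L, b + 1L)], xout = tn[a:b])$y
        }
      }
    }
    # 2. centered moving average, symmetric edge truncation
    w <- centered_ma(w, cfg$window)
    # 3. antitonic projection
    ok <- which(!is.na(w))
    w[ok] <- pav_antitonic(w[ok])
    out$weight_kg[idx] <- w
  }
  out
}

# ---------------------------------------------------------------------------
# Consumption

#' Per-interval and daily feed consumption from a cleaned weight series
#'
#' Consumption between consecutive readings is the weight decrease within a
#' segment; the interval spanning a refill contributes
#' `max(0, pre - (post - load))` where `load` is the refill mass. Daily
#' aggregates prorate each interval's consumption uniformly over the time it
#' spans; an interval longer than the interpolation gap limit is assigned
#' entirely to the day it ends.
#'
#' @param cleaned a cleaned weight series (see [clean_series()]).
#' @param refills optional data.frame with columns `segment` (the segment a
#'   refill opens) and `load_mass` (kg); without it refill boundaries
#'   contribute nothing.
#' @param cfg a [cleaning_config()] (for the gap rule).
#' @param nominal_interval reading cadence in seconds (default 7200).
#' @return list of class `consumption` with `intervals` (t_start, t_end,
#'   consumed_kg, boundary) and `daily` (date, consumed_kg).
#' @export
compute_consumption <- function(cleaned, refills = NULL,
                                cfg = cleaning_config(),
                                nominal_interval = 7200) {
  rows <- which(!is.na(cleaned$weight_kg))
  if (length(rows) < 2) {
    return(structure(list(
      intervals = data.frame(t_start = as.POSIXct(character(), tz = "UTC"),
                             t_end = as.POSIXct(character(), tz = "UTC"),
                             consumed_kg = numeric(), boundary = logical()),
      daily = data.frame(date = as.Date(character()), consumed_kg = numeric())),
      class = "consumption"))
  }
  load_for_segment <- function(s) {
    if (is.null(refills) || !nrow(refills)) return(0)
    m <- refills$load_mass[refills$segment == s]
    if (length(m)) m[1] else 0
  }
  p <- rows[-length(rows)]
  q <- rows[-1]
  wp <- cleaned$weight_kg[p]; wq <- cleaned$weight_kg[q]
  sp <- cleaned$segment[p]; sq <- cleaned$segment[q]
  boundary <- sp != sq
  consumed <- wp - wq
  if (any(boundary)) {
    for (i in which(boundary)) {
      load <- sum(vapply((sp[i] + 1L):sq[i], load_for_segment, numeric(1)))
      ci <- wp[i] - (wq[i] - load)
      if (ci < 0) {
        warning("negative consumption across refill boundary floored at 0")
        ci <- 0
      }
      consumed[i] <- ci
    }
  }
  if (any(consumed[!boundary] < -1e-6)) {
    stop("internal invariant violation: negative consumption within a ",
         "segment after cleaning")
  }
  consumed[consumed < 0] <- 0

  intervals <- data.frame(t_start = cleaned$timestamp[p],
                          t_end = cleaned$timestamp[q],
                          consumed_kg = consumed, boundary = boundary)

  # daily aggregation
  gap_limit <- (cfg$max_gap_interpolate + 1L) * nominal_interval
  day_tab <- new.env(parent = emptyenv())
  add_day <- function(d, x) {
    key <- format(d)
    assign(key, x + (if (exists(key, day_tab)) get(key, day_tab) else 0),
           envir = day_tab)
  }
  ta <- as.numeric(intervals$t_start); tb <- as.numeric(intervals$t_end)
  for (i in seq_len(nrow(intervals))) {
    ci <- intervals$consumed_kg[i]
    dur <- tb[i] - ta[i]
    if (dur > gap_limit) {
      add_day(as.Date(intervals$t_end[i] - 1e-3, tz = "UTC"), ci)
      next
    }
    d0 <- floor(ta[i] / SECONDS_PER_DAY)
    d1 <- floor((tb[i] - 1e-3) / SECONDS_PER_DAY)
    if (d0 == d1) {
      add_day(as.Date(intervals$t_start[i], tz = "UTC"), ci)
    } else {
      for (d in d0:d1) {
        lo <- max(ta[i], d * SECONDS_PER_DAY)
        hi <- min(tb[i], (d + 1) * SECONDS_PER_DAY)
        add_day(as.Date(as.POSIXct(lo, origin = "1970-01-01", tz = "UTC"),
                        tz = "UTC"),
                ci * (hi - lo) / dur)
      }
    }
  }
  keys <- sort(ls(day_tab))
  daily <- data.frame(date = as.Date(keys),
                      consumed_kg = vapply(keys, get, numeric(1),
                                           envir = day_tab))
  rownames(daily) <- NULL
  structure(list(intervals = intervals, daily = daily), class = "consumption")
}

# ---------------------------------------------------------------------------
# Orchestrator

#' Run the full silo pipeline on a level series
#'
#' Steps: refill detection (on a smoothed copy of the volume series), raw
#' jump localisation and local-regression refinement of each jump, matching
#' against declared refills, sequential density estimation with mass-weighted
#' blending, weight-series construction, per-segment cleaning, and
#' consumption computation.
#'
#' @param series a [level_series()].
#' @param batch a [batch_config()] (provides silo geometry, default density
#'   and declared refills).
#' @param cfg a [cleaning_config()].
#' @return list of class `silo_result`: `weights` (raw weight series),
#'   `cleaned`, `consumption`, `refills` (detected events with refined
#'   deltas, matched declared weights, load densities and masses),
#'   `densities` (per segment), `missing_by_week`.
#' @export
process_silo <- function(series, batch, cfg = cleaning_config()) {
  stopifnot(inherits(series, "level_series"), inherits(batch, "batch_config"))
  silo <- batch$silo
  n <- nrow(series)
  tnum <- as.numeric(series$timestamp)
  vols <- rep(NA_real_, n)
  ok <- series$quality == "ok"
  vols[ok] <- level_to_volume(series$level_fraction[ok], silo)

  # fill all gaps for detection/localisation only
  vols_filled <- vols
  if (anyNA(vols_filled) && sum(!is.na(vols_filled)) >= 2) {
    vols_filled <- stats::approx(tnum[!is.na(vols)], vols[!is.na(vols)],
                                 xout = tnum, rule = 2)$y
  }
  smooth_frac <- centered_ma(vols_filled, cfg$window) / silo$usable_volume
  smooth_frac <- pmin(pmax(smooth_frac, 0), 1)
  det_series <- level_series(series$timestamp, smooth_frac,
                             nominal_interval = attr(series, "nominal_interval"))
  detected <- detect_refills(det_series, silo, cfg)
  runs <- attr(detected, "runs")

  # locate raw jumps, refine deltas / pre-refill volumes
  n_ev <- nrow(detected)
  jump_right <- integer(n_ev)
  detected$delta_refined <- rep(NA_real_, n_ev)
  detected$volume_pre <- rep(NA_real_, n_ev)
  detected$volume_left <- rep(NA_real_, n_ev)
  detected$volume_right <- rep(NA_real_, n_ev)
  if (n_ev) {
    for (i in seq_len(n_ev)) {
      prev_hi <- if (i > 1) jump_right[i - 1L] else 0L
      next_lo <- if (i < n_ev) runs$start_row[i + 1L] else n + 1L
      rr <- refine_refill(tnum, vols, vols_filled,
                          max(runs$start_row[i], 1L),
                          min(runs$end_row[i], n),
                          prev_hi, next_lo)
      jump_right[i] <- rr$jump_right
      detected$delta_refined[i] <- rr$delta_refined
      detected$volume_pre[i] <- rr$volume_pre
      detected$volume_left[i] <- rr$volume_left
      detected$volume_right[i] <- rr$volume_right
      detected$timestamp[i] <- series$timestamp[rr$jump_left]
    }
  }
  detected <- match_refills(detected, batch$refills)

  # segment ids: each jump_right row opens a new segment
  segment <- findInterval(seq_len(n), sort(jump_right)) + 1L

  # sequential density chain
  dens <- numeric(n_ev + 1L)
  dens[1] <- batch$density$default_density
  detected$load_density <- rep(NA_real_, n_ev)
  detected$load_mass <- rep(NA_real_, n_ev)
  detected$segment <- if (n_ev) seq_len(n_ev) + 1L else integer(0)
  if (n_ev) {
    for (i in seq_len(n_ev)) {
      ev <- detected[i, ]
      ev$detected_volume_delta <- ev$delta_refined
      if (is.na(ev$detected_volume_delta) || ev$detected_volume_delta <= 0) {
        # refinement failed (e.g. long gap at the jump); raw run gain
        ev$detected_volume_delta <- detected$detected_volume_delta[i]
        detected$delta_refined[i] <- ev$detected_volume_delta
      }
      rho_load <- estimate_density(ev, batch$density)
      m_load <- if (!is.na(ev$declared_weight)) ev$declared_weight else
        ev$delta_refined * rho_load
      m_rem <- max(ev$volume_pre, 0) * dens[i]
      # post-refill density = blended contents mass over observed post
      # volume; identical to the mass-weighted blend expressed through the
      # observed volume jump, and exact whenever declared weight and the
      # level trace are
      v_post <- max(ev$volume_pre, 0) + ev$delta_refined
      dens[i + 1L] <- if (v_post > 0) (m_rem + m_load) / v_post else dens[i]
      detected$load_density[i] <- rho_load
      detected$load_mass[i] <- m_load
    }
  }
  densities <- data.frame(segment = seq_len(n_ev + 1L), density = dens)

  weights <- data.frame(timestamp = series$timestamp,
                        weight_kg = volume_to_weight(ifelse(is.na(vols), NA,
                                                            vols),
                                                     dens[segment]),
                        segment = segment)
  class(weights) <- c("weight_series", "data.frame")
  cleaned <- clean_series(weights, cfg)
  # anchor the two readings adjacent to each refill jump at the local
  # regression fits: these edge values set every segment's consumption total
  # and, unlike the edge-truncated moving average, they average noise over
  # the whole fit window (on noise-free data they equal the raw readings)
  if (n_ev) {
    for (i in seq_len(n_ev)) {
      jl <- jump_right[i] - 1L
      jr <- jump_right[i]
      a_left <- detected$volume_left[i] * dens[i]
      a_right <- detected$volume_right[i] * dens[i + 1L]
      prev_ok <- which(!is.na(cleaned$weight_kg) & segment == segment[jl] &
                         seq_len(n) < jl)
      if (length(prev_ok)) a_left <- min(a_left,
                                         cleaned$weight_kg[max(prev_ok)])
      next_ok <- which(!is.na(cleaned$weight_kg) & segment == segment[jr] &
                         seq_len(n) > jr)
      if (length(next_ok)) a_right <- max(a_right,
                                          cleaned$weight_kg[min(next_ok)])
      cleaned$weight_kg[jl] <- a_left
      cleaned$weight_kg[jr] <- a_right
    }
  }
  # anchor the series start and end with the same local fits
  ok_rows <- which(!is.na(cleaned$weight_kg))
  if (length(ok_rows) >= 2) {
    first_seg <- which(segment == segment[1] &
                         tnum <= tnum[1] + 3 * SECONDS_PER_DAY)
    a0 <- pwl_predict(tnum[first_seg], vols[first_seg], tnum[1]) * dens[1]
    nxt <- ok_rows[ok_rows > 1L & segment[ok_rows] == segment[1]]
    if (!is.na(a0)) {
      if (length(nxt)) a0 <- max(a0, cleaned$weight_kg[min(nxt)])
      cleaned$weight_kg[1] <- a0
    }
    last_seg <- which(segment == segment[n] &
                        tnum >= tnum[n] - 3 * SECONDS_PER_DAY)
    a1 <- pwl_predict(tnum[last_seg], vols[last_seg], tnum[n]) *
      dens[segment[n]]
    prv <- ok_rows[ok_rows < n & segment[ok_rows] == segment[n]]
    if (!is.na(a1)) {
      if (length(prv)) a1 <- min(a1, cleaned$weight_kg[max(prv)])
      cleaned$weight_kg[n] <- a1
    }
  }
  refill_loads <- data.frame(segment = detected$segment,
                             load_mass = detected$load_mass)
  consumption <- compute_consumption(cleaned, refill_loads, cfg,
                                     attr(series, "nominal_interval"))

  # weekly missing fraction (for data-quality alerts)
  wk <- week_of_day(day_index(series$timestamp, batch$start_date))
  miss <- tapply(series$quality == "missing", wk, mean)
  missing_by_week <- data.frame(week = as.integer(names(miss)),
                                missing_fraction = as.numeric(miss))

  structure(list(weights = weights, cleaned = cleaned,
                 consumption = consumption, refills = detected,
                 densities = densities, missing_by_week = missing_by_week),
            class = "silo_result")
}
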