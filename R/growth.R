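# Feed-intake and growth curves: logistic accumulated feed intake (AFI) as a
# function of age, Gompertz body weight as a function of AFI, cubic-polynomial
# weight variance, per-entry subgroup distributions and the merged 5-kg-bin
# batch weight distribution.

#' Theoretical accumulated feed intake
#'
#' `AFI(age) = N * A_feed / (1 + exp(-b_feed * age))`, the logistic curve of
#' cumulative feed intake against the animals' age in weeks. With
#' `n_animals = 1` this is the per-animal curve; the batch value is `N` times
#' it. Strictly increasing in age with asymptote `N * A_feed`.
#'
#' @param age_weeks age in weeks, >= 0 (vectorised).
#' @param params a [growth_params()].
#' @param n_animals head count (default 1).
#' @return accumulated feed intake in kg.
#' @export
theoretical_afi <- function(age_weeks, params, n_animals = 1) {
  if (any(age_weeks < 0)) stop("age_weeks must be >= 0")
  if (any(n_animals < 1)) stop("n_animals must be >= 1")
  n_animals * params$A_feed / (1 + exp(-params$b_feed * age_weeks))
}

#' Linear ADG x FCR intake cross-check
#'
#' `AFI_lin(t) = ADG * FCR * 7 t` kg per animal: the conventional
#' technical-parameter estimate of cumulative intake, reported alongside the
#' logistic curve as a secondary cross-check.
#'
#' @param week 0-based week index (vectorised).
#' @param params a [growth_params()]; needs `adg` and `fcr`.
#' @return kg per animal, `NA` if ADG or FCR is unset.
#' @export
linear_afi <- function(week, params) {
  params$adg * params$fcr * 7 * week
}

#' Gompertz average body weight from accumulated feed intake
#'
#' `AW = A_weight * exp(-exp(b_weight - k_weight * AFI))`: average body
#' weight (kg) of a (sub)group given its cumulative per-animal feed intake
#' since entry. Strictly increasing in AFI and bounded by `A_weight`.
#'
#' @param afi_per_animal cumulative feed intake per animal, kg, >= 0
#'   (vectorised).
#' @param params a [growth_params()].
#' @return average body weight, kg.
#' @export
gompertz_weight <- function(afi_per_animal, params) {
  if (any(afi_per_animal < 0)) stop("afi_per_animal must be >= 0")
  params$A_weight * exp(-exp(params$b_weight -
                               params$k_weight * afi_per_animal))
}

#' Weight variance at a given week
#'
#' Cubic polynomial `c0 + c1 t + c2 t^2 + c3 t^3` (kg^2) in the weeks elapsed
#' since the subgroup's entry; positivity over the horizon is enforced at
#' [growth_params()] construction.
#'
#' @param week weeks since entry, >= 0 (vectorised).
#' @param params a [growth_params()].
#' @return variance, kg^2.
#' @export
weight_variance <- function(week, params) {
  if (any(week < 0)) stop("week must be >= 0")
  c0 <- params$var_coeffs
  c0[1] + c0[2] * week + c0[3] * week^2 + c0[4] * week^3
}

# per-entry head counts on a day, departures attributed proportionally
subgroup_headcounts <- function(config, day) {
  if (is.numeric(day)) day <- config$start_date + day
  day <- as.Date(day)
  n <- ifelse(config$entries$entry_date <= day, config$entries$n_animals, 0)
  dep <- config$departures
  if (nrow(dep)) {
    for (i in which(dep$date <= day)) {
      tot <- sum(n)
      if (tot > 0) n <- n - dep$n_removed[i] * n / tot
    }
  }
  pmax(n, 0)
}

#' Weekly intake series: sensor-based and theoretical AFI
#'
#' Turns daily batch consumption into weekly cumulative per-animal intake and
#' sets the theoretical counterpart beside it. Per-animal daily intake is the
#' daily batch consumption divided by the animals present that day; the
#' theoretical per-animal intake on a day is the head-weighted mean over the
#' entry subgroups of the day-differenced logistic AFI curve at each
#' subgroup's age. Both are accumulated over half-open weeks
#' `[7t, 7t+7)` since the batch start.
#'
#' @param consumption a `consumption` object from [compute_consumption()] or
#'   [process_silo()].
#' @param config a [batch_config()].
#' @param weeks number of weeks to report; default all complete weeks
#'   covered by the consumption data.
#' @return data.frame of class `intake_series` with columns `week`,
#'   `afi_sensor_kg`, `afi_theory_kg`, `afi_linear_kg`, `deviation`,
#'   `n_present` (average head count that week). A `daily` attribute carries
#'   the day-level table.
#' @export
intake_series <- function(consumption, config, weeks = NULL) {
  if (inherits(consumption, "silo_result")) {
    consumption <- consumption$consumption
  }
  daily <- consumption$daily
  day <- as.integer(daily$date - config$start_date)
  keep <- day >= 0
  daily <- daily[keep, , drop = FALSE]
  day <- day[keep]
  if (!length(day)) stop("consumption does not cover the batch period")
  max_day <- max(day)
  if (is.null(weeks)) weeks <- (max_day + 1L) %/% 7L
  if (weeks < 1) stop("consumption covers less than one full week")
  n_days <- 7L * weeks
  cons <- numeric(n_days)
  cons[day[day < n_days] + 1L] <- daily$consumed_kg[day < n_days]
  dvec <- 0:(n_days - 1L)
  n_present_day <- animals_present(config, config$start_date + dvec)
  if (any(n_present_day == 0 & cons > 1e-9)) {
    stop("positive consumption on a day with zero animals present")
  }
  per_animal <- ifelse(n_present_day > 0, cons / n_present_day, 0)

  # theoretical per-animal daily intake, head-weighted over subgroups
  g <- function(age) config$growth$A_feed /
    (1 + exp(-config$growth$b_feed * age))
  entry_day <- as.integer(config$entries$entry_date - config$start_date)
  theory <- numeric(n_days)
  heads <- vapply(dvec, function(d) subgroup_headcounts(config, d),
                  numeric(nrow(config$entries)))
  heads <- matrix(heads, nrow = nrow(config$entries))
  for (d in seq_len(n_days)) {
    hv <- heads[, d]
    tot <- sum(hv)
    if (tot <= 0) next
    contrib <- 0
    for (i in seq_len(nrow(config$entries))) {
      e <- entry_day[i]
      if (dvec[d] < e || hv[i] <= 0) next
      a0 <- config$entries$age_weeks[i] + (dvec[d] - e) / 7
      contrib <- contrib + hv[i] * (g(a0 + 1 / 7) - g(a0))
    }
    theory[d] <- contrib / tot
  }

  wk <- 0:(weeks - 1L)
  cuts <- 7L * (wk + 1L)
  afi_sensor <- vapply(cuts, function(k) sum(per_animal[seq_len(k)]),
                       numeric(1))
  afi_theory <- vapply(cuts, function(k) sum(theory[seq_len(k)]), numeric(1))
  n_present_wk <- vapply(wk, function(t) {
    mean(n_present_day[(7 * t + 1):(7 * t + 7)])
  }, numeric(1))

  out <- data.frame(week = wk,
                    afi_sensor_kg = afi_sensor,
                    afi_theory_kg = afi_theory,
                    afi_linear_kg = linear_afi(wk, config$growth),
                    n_present = n_present_wk)
  dev <- deviation_series(out)
  out$deviation <- dev$deviation
  attr(out, "daily") <- data.frame(day = dvec,
                                   date = config$start_date + dvec,
                                   consumed_kg = cons,
                                   n_present = n_present_day,
                                   per_animal_kg = per_animal,
                                   theory_per_animal_kg = theory)
  class(out) <- c("intake_series", "data.frame")
  out
}

#' Weekly deviation between sensor-based and theoretical intake
#'
#' Relative deviation `(sensor - theory) / theory` per week. By default it is
#' computed on weekly intake increments (the difference of consecutive
#' cumulative AFI values), which reacts within a week to a feeding change;
#' `cumulative = TRUE` compares the cumulative AFI columns directly. A week
#' where both quantities are zero has deviation 0.
#'
#' @param intake an [intake_series()] (or any data.frame with `week`,
#'   `afi_sensor_kg`, `afi_theory_kg`).
#' @param cumulative compare cumulative AFI instead of weekly increments.
#' @return data.frame with columns `week`, `deviation`.
#' @export
deviation_series <- function(intake, cumulative = FALSE) {
  s <- intake$afi_sensor_kg
  th <- intake$afi_theory_kg
  if (!cumulative) {
    s <- diff(c(0, s))
    th <- diff(c(0, th))
  }
  dev <- ifelse(th == 0, ifelse(s == 0, 0, Inf * sign(s)), (s - th) / th)
  data.frame(week = intake$week, deviation = dev)
}

#' Per-entry subgroup weight distributions at a week
#'
#' Applies the Gompertz curve to each entry subgroup's accumulated feed
#' intake (offset by its entry date, and for the theoretical source by its
#' entry age), with variance from the cubic polynomial at the subgroup's own
#' elapsed weeks and head counts from the inventory (departures attributed
#' proportionally to subgroup size).
#'
#' @param intake an [intake_series()].
#' @param config a [batch_config()].
#' @param week 0-based week index, present in `intake`.
#' @param source `"sensor"` (cumulative per-animal sensor intake since the
#'   subgroup's entry week) or `"theory"` (exact logistic curve at the
#'   subgroup's age).
#' @return data.frame of class `subgroup_distribution` with columns
#'   `entry_index`, `week`, `mean_kg`, `variance_kg2`, `n_alive`.
#' @export
subgroup_distributions <- function(intake, config, week,
                                   source = c("sensor", "theory")) {
  source <- match.arg(source)
  if (!week %in% intake$week) stop("week ", week, " not in intake series")
  g <- function(age) config$growth$A_feed /
    (1 + exp(-config$growth$b_feed * age))
  entry_week <- week_of_day(as.integer(config$entries$entry_date -
                                         config$start_date))
  heads <- subgroup_headcounts(config, 7L * week + 6L)
  rows <- which(entry_week <= week)
  afi_col <- intake$afi_sensor_kg
  out <- do.call(rbind, lapply(rows, function(i) {
    e <- entry_week[i]
    elapsed <- week - e
    if (source == "sensor") {
      base <- if (e > 0) afi_col[intake$week == e - 1L] else 0
      afi <- afi_col[intake$week == week] - base
    } else {
      a <- config$entries$age_weeks[i]
      afi <- g(a + elapsed + 1) - g(a)
    }
    data.frame(entry_index = i, week = week,
               mean_kg = gompertz_weight(max(afi, 0), config$growth),
               variance_kg2 = weight_variance(elapsed, config$growth),
               n_alive = heads[i])
  }))
  rownames(out) <- NULL
  class(out) <- c("subgroup_distribution", "data.frame")
  out
}

#' Merge subgroup distributions and bin into weight ranges
#'
#' The batch weight distribution is the head-count-weighted mixture of the
#' per-subgroup normal distributions. Expected counts per half-open bin
#' `[L, L + width)` are `sum_i n_i (Phi((L + width - m_i)/s_i) -
#' Phi((L - m_i)/s_i))`; the bins cover every component mean +/- 4 standard
#' deviations of the widest component, so the unbinned tail mass is below
#' 1e-4 of the head count.
#'
#' @param components a [subgroup_distributions()] data.frame.
#' @param bin_width bin width in kg (default 5).
#' @return list of class `weight_distribution` with `components`,
#'   `bin_width`, `bins` (bin_low_kg, bin_high_kg, expected_count),
#'   `total_count`, and `tail_below_zero` (expected animals below 0 kg under
#'   the untruncated normals, reported for the summary).
#' @export
merge_and_bin <- function(components, bin_width = 5) {
  if (is.null(components) || nrow(components) == 0) {
    stop("no subgroup components to merge")
  }
  m <- components$mean_kg
  sd <- sqrt(components$variance_kg2)
  n <- components$n_alive
  sd_max <- max(sd)
  lo <- floor((min(m) - 4 * sd_max) / bin_width) * bin_width
  hi <- ceiling((max(m) + 4 * sd_max) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- numeric(length(edges) - 1L)
  for (i in seq_along(m)) {
    p <- stats::pnorm(edges, m[i], sd[i])
    counts <- counts + n[i] * diff(p)
  }
  structure(list(components = components, bin_width = bin_width,
                 bins = data.frame(bin_low_kg = edges[-length(edges)],
                                   bin_high_kg = edges[-1],
                                   expected_count = counts),
                 total_count = sum(n),
                 tail_below_zero = sum(n * stats::pnorm(0, m, sd))),
            class = "weight_distribution")
}
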