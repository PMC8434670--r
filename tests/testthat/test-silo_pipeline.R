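test_that("linear geometry maps fractions to volume proportionally", {
  s <- silo_spec(20)
  expect_equal(level_to_volume(0, s), 0)
  expect_equal(level_to_volume(1, s), 20)
  expect_equal(level_to_volume(0.25, s), 5)
  expect_error(level_to_volume(1.2, s), "outside")
})

test_that("cylinder-cone volume agrees with numeric integration of the cross-section", {
  r <- 1.25; hc <- 2; hb <- 6
  vtot <- pi * r^2 * (hc / 3 + hb)
  s <- silo_spec(vtot, "cylinder_cone", body_height = hb, cone_height = hc,
                 diameter = 2.5)
  area <- function(h) ifelse(h <= hc, pi * (r * h / hc)^2, pi * r^2)
  for (frac in c(0.1, 0.2, 0.5, 0.8, 1)) {
    h_fill <- frac * (hc + hb)
    hh <- seq(0, h_fill, length.out = 200001)
    v_oracle <- sum((area(hh[-1]) + area(hh[-length(hh)])) / 2 * diff(hh))
    expect_equal(level_to_volume(frac, s), v_oracle, tolerance = 1e-9)
  }
  expect_equal(level_to_volume(0, s), 0)
  expect_equal(level_to_volume(1, s), vtot)
  # monotone in the fraction
  v <- level_to_volume(seq(0, 1, by = 0.01), s)
  expect_true(all(diff(v) > 0))
})

test_that("volume to weight is an exact product with guards", {
  expect_equal(volume_to_weight(20, 650), 13000)
  expect_equal(volume_to_weight(0, 640), 0)
  expect_equal(volume_to_weight(10, 640), 6400)
  expect_error(volume_to_weight(10, -1), "density")
})

test_that("refill detection finds exactly the injected jumps and matches the run oracle", {
  silo <- silo_spec(20)
  cfg <- cleaning_config(refill_threshold = 1)
  t0 <- as.POSIXct("2021-03-01", tz = "UTC")

  # strictly decreasing series: nothing
  s <- level_series(t0 + 7200 * 0:99, seq(0.9, 0.4, length.out = 100))
  expect_equal(nrow(detect_refills(s, silo, cfg)), 0)

  # single jump of +0.5 capacity at index 50 (net of the drain step)
  lv <- seq(0.7, 0.3, length.out = 100)
  lv[51:100] <- lv[51:100] + 0.5
  s <- level_series(t0 + 7200 * 0:99, lv)
  ev <- detect_refills(s, silo, cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$timestamp, s$timestamp[50])
  expect_equal(ev$detected_volume_delta, (lv[51] - lv[50]) * 20,
               tolerance = 1e-9)
  expect_equal(ev$detected_volume_delta, 10, tolerance = 0.1)

  # two refills amid noise, against the exhaustive run oracle
  set.seed(101)
  lv <- 0.9 - cumsum(rep(0.0018, 500)) + rnorm(500, 0, 0.0025) # +-0.05 m^3
  lv[250:500] <- lv[250:500] + 0.35                            # 7 m^3
  lv[420:500] <- lv[420:500] + 0.40                            # 8 m^3
  s <- level_series(t0 + 7200 * 0:499, lv)
  ev <- detect_refills(s, silo, cfg)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$detected_volume_delta, c(7, 8), tolerance = 0.2)
  orc <- oracle_increase_runs(lv * 20, 1)
  expect_equal(nrow(ev), nrow(orc))
  expect_equal(ev$detected_volume_delta, orc$gain, tolerance = 1e-9)
  expect_equal(which(s$timestamp %in% ev$timestamp), orc$start)
})

test_that("refill detection equals exhaustive run enumeration on long random walks", {
  silo <- silo_spec(20)
  t0 <- as.POSIXct("2021-03-01", tz = "UTC")
  for (seed in 1:3) {
    set.seed(seed)
    lv <- pmin(pmax(0.5 + cumsum(rnorm(10000, 0, 0.01)), 0), 1)
    s <- level_series(t0 + 7200 * (0:9999), lv)
    for (thr in c(0.5, 1, 2)) {
      ev <- detect_refills(s, silo, cleaning_config(refill_threshold = thr))
      orc <- oracle_increase_runs(lv * 20, thr)
      n_orc <- if (is.null(orc)) 0 else nrow(orc)
      expect_equal(nrow(ev), n_orc)
      if (n_orc) expect_equal(ev$detected_volume_delta, orc$gain,
                              tolerance = 1e-9)
    }
  }
})

test_that("density estimation uses declared weight, falls back, and blends by mass", {
  ds <- density_state(640)
  ev <- list(declared_weight = 6500, detected_volume_delta = 10)
  expect_equal(estimate_density(ev, ds), 650)
  ev2 <- list(declared_weight = NA_real_, detected_volume_delta = 10)
  expect_equal(estimate_density(ev2, ds), 640)
  ev3 <- list(declared_weight = 6500, detected_volume_delta = 0)
  expect_error(estimate_density(ev3, ds), "calibrate")
  expect_equal(blend_density(2000, 600, 6000, 660), 645)
})

make_wseries <- function(w, seg = 1L) {
  out <- data.frame(timestamp = as.POSIXct("2021-03-01", tz = "UTC") +
                      7200 * seq_along(w),
                    weight_kg = w, segment = seg)
  class(out) <- c("weight_series", "data.frame")
  out
}

test_that("the smoother fixes constants, preserves affine segments, and matches the brute-force oracle", {
  cfg <- cleaning_config(window = 13)

  ws <- make_wseries(rep(5000, 50))
  expect_equal(clean_series(ws, cfg)$weight_kg, rep(5000, 50))

  aff <- seq(12000, 8000, length.out = 80)
  ws <- make_wseries(aff)
  expect_equal(clean_series(ws, cfg)$weight_kg, aff, tolerance = 1e-12)

  set.seed(7)
  truth <- 12000 - 15 * (1:200)
  noisy <- truth + rnorm(200, 0, 30)
  ws <- make_wseries(noisy)
  got <- clean_series(ws, cfg)$weight_kg
  want <- oracle_pav_antitonic(oracle_ma(noisy, 13))
  expect_equal(got, want, tolerance = 1e-9)
  expect_lt(sqrt(mean((got - truth)^2)), sqrt(mean((noisy - truth)^2)))
  expect_true(all(diff(got) <= 1e-9))
})

test_that("the oracle equivalence holds across window widths on 1000-point segments", {
  for (seed in 1:3) {
    set.seed(seed)
    noisy <- 15000 - 12 * (1:1000) + rnorm(1000, 0, 50)
    for (w in c(5, 13, 25)) {
      got <- clean_series(make_wseries(noisy), cleaning_config(window = w))
      want <- oracle_pav_antitonic(oracle_ma(noisy, w))
      expect_equal(got$weight_kg, want, tolerance = 1e-9)
    }
  }
})

test_that("short gaps are interpolated, long gaps are left open", {
  cfg <- cleaning_config(window = 3, max_gap_interpolate = 2)
  w <- seq(10000, 9000, length.out = 21)
  w[5:6] <- NA            # short gap: interpolated
  w[10:14] <- NA          # long gap (5 > 2): left missing
  got <- clean_series(make_wseries(w), cfg)$weight_kg
  expect_false(anyNA(got[5:6]))
  expect_true(all(is.na(got[10:14])))
})

test_that("a too-short segment passes through with a warning", {
  ws <- make_wseries(c(5000, NA, NA), seg = 1L)
  expect_warning(out <- clean_series(ws, cleaning_config()), "fewer than 2")
  expect_equal(out$weight_kg, ws$weight_kg)
})

test_that("consumption differences, refill mass balance, and daily totals are exact", {
  ws <- make_wseries(c(10000, 9900, 9850))
  cons <- compute_consumption(ws)
  expect_equal(cons$intervals$consumed_kg, c(100, 50))

  ws <- make_wseries(c(2000, 8450), seg = c(1L, 2L))
  cons <- compute_consumption(ws, refills = data.frame(segment = 2L,
                                                       load_mass = 6500))
  expect_equal(cons$intervals$consumed_kg, 50)

  # 7-day constant-consumption trace, no noise: daily aggregates exact
  sc <- simulate_scenario(scenario_config(
    seed = 2, horizon_weeks = 1, noise_sd = 0, missing_prob = 0,
    constant_intake_kg_day = 2, marketing_weight = Inf))
  res <- process_silo(sc$series, sc$batch)
  d <- res$consumption$daily
  dd <- as.integer(d$date - sc$batch$start_date)
  expect_equal(d$consumed_kg, sc$truth$daily_batch_consumption[dd + 1],
               tolerance = 1e-6 / 1200)
})

test_that("mass balance holds through the full pipeline on noisy input", {
  sc <- simulate_scenario(scenario_config(seed = 12))
  res <- suppressWarnings(process_silo(sc$series, sc$batch))
  est <- sum(res$consumption$daily$consumed_kg)
  expect_lt(abs(est - sc$truth$total_consumption),
            0.005 * sc$truth$total_consumption)
  # cleaned series non-increasing within every segment
  for (s in unique(res$cleaned$segment)) {
    w <- res$cleaned$weight_kg[res$cleaned$segment == s]
    w <- w[!is.na(w)]
    expect_true(all(diff(w) <= 1e-9))
  }
})

test_that("the smoother is idempotent on smooth monotone segments away from edges", {
  cfg <- cleaning_config(window = 13)
  y <- 12000 - 14 * (1:120)
  once <- clean_series(make_wseries(y), cfg)$weight_kg
  twice <- clean_series(make_wseries(once), cfg)$weight_kg
  core <- 7:114
  expect_equal(twice[core], once[core], tolerance = 1e-9)
})
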