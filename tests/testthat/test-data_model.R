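test_that("level series CSV parsing handles good rows, missing cells and duplicates", {
  p <- tmp_path("readings.csv")
  writeLines(c("timestamp,level_fraction",
               "2021-03-01T00:00:00Z,0.9",
               "2021-03-01T02:00:00Z,0.85",
               "2021-03-01T04:00:00Z,0.8"), p)
  s <- read_level_series(p)
  expect_s3_class(s, "level_series")
  expect_equal(nrow(s), 3)
  expect_equal(s$level_fraction, c(0.9, 0.85, 0.8))
  expect_true(!is.unsorted(s$timestamp))

  writeLines(c("timestamp,level_fraction",
               "2021-03-01T00:00:00Z,0.9",
               "2021-03-01T02:00:00Z,",
               "2021-03-01T04:00:00Z,0.8"), p)
  s <- read_level_series(p)
  expect_equal(nrow(s), 3)
  expect_equal(s$quality, c("ok", "missing", "ok"))
  expect_true(is.na(s$level_fraction[2]))

  writeLines(c("timestamp,level_fraction",
               "2021-03-01T00:00:00Z,0.9",
               "2021-03-01T00:00:00Z,0.85"), p)
  expect_error(read_level_series(p), "2021-03-01T00:00:00Z")
})

test_that("level series JSON input matches the CSV reader", {
  pj <- tmp_path("readings.json")
  jsonlite::write_json(data.frame(timestamp = c("2021-03-01T00:00:00Z",
                                                "2021-03-01T02:00:00Z"),
                                  level_fraction = c(0.5, 0.45)),
                       pj, dataframe = "rows")
  s <- read_level_series(pj)
  expect_equal(s$level_fraction, c(0.5, 0.45))
})

test_that("level series write/read round-trips including missing rows", {
  s <- level_series(as.POSIXct("2021-03-01", tz = "UTC") + 7200 * 0:5,
                    c(0.9, 0.85, NA, 0.8123456789, 0.7, 0.65))
  p <- tmp_path("rt.csv")
  write_level_series(s, p)
  s2 <- read_level_series(p)
  expect_equal(s2$level_fraction, s$level_fraction, tolerance = 1e-12)
  expect_equal(s2$quality, s$quality)
  expect_equal(as.numeric(s2$timestamp), as.numeric(s$timestamp))
})

make_growth <- function() {
  growth_params(A_feed = 1100, b_feed = 0.065, A_weight = 230,
                b_weight = 0.7115, k_weight = 0.00481,
                var_coeffs = c(9, 2, 0.35, 0), adg = 0.8, fcr = 2.6)
}

make_config <- function(entries = NULL, departures = NULL) {
  if (is.null(entries)) {
    entries <- data.frame(entry_date = as.Date("2021-03-01"),
                          n_animals = 600, avg_weight = 30, age_weeks = 10)
  }
  batch_config("b1", entries, departures, NULL, make_growth(),
               density_state(640), silo_spec(20))
}

test_that("animals_present does additive bookkeeping with inclusive boundaries", {
  cfg <- make_config(departures = data.frame(date = as.Date("2021-03-01") + 80,
                                             n_removed = 100,
                                             abattoir_weight = 11000))
  expect_equal(animals_present(cfg, as.Date("2021-03-01") + 85), 500L)
  expect_equal(animals_present(cfg, as.Date("2021-03-01")), 600L)
  expect_equal(animals_present(cfg, as.Date("2021-03-01") + 80), 500L)
  expect_error(animals_present(cfg, as.Date("2021-02-28")), "batch start")
})

test_that("departures exceeding entries are rejected at config load", {
  expect_error(
    make_config(departures = data.frame(date = as.Date("2021-03-10"),
                                        n_removed = 700,
                                        abattoir_weight = 1)),
    "exceed")
})

test_that("animals_present is a non-negative step function ending at the net count", {
  cfg <- make_config(
    entries = data.frame(entry_date = as.Date("2021-03-01") + c(0, 7),
                         n_animals = c(400, 200), avg_weight = 30,
                         age_weeks = 10),
    departures = data.frame(date = as.Date("2021-03-01") + c(100, 110),
                            n_removed = c(100, 100),
                            abattoir_weight = c(11000, 11500)))
  days <- as.Date("2021-03-01") + 0:125
  counts <- animals_present(cfg, days)
  expect_true(all(counts >= 0))
  expect_equal(counts[length(counts)], 600L - 200L)
  expect_equal(counts[1], 400L)
})

test_that("silo geometry validation catches inconsistent cylinder-cone volumes", {
  r <- 1.25
  v_ok <- pi * r^2 * (2 / 3 + 6)
  expect_silent(silo_spec(v_ok, "cylinder_cone", body_height = 6,
                          cone_height = 2, diameter = 2.5))
  expect_error(silo_spec(v_ok * 1.05, "cylinder_cone", body_height = 6,
                         cone_height = 2, diameter = 2.5), "0.1%")
})

test_that("variance polynomial must stay positive across the horizon", {
  expect_error(growth_params(1100, 0.065, 230, 0.7115, 0.00481,
                             var_coeffs = c(10, 0, 0, -1)),
               "not positive")
  g <- growth_params(1100, 0.065, 230, 0.7115, 0.00481, c(9, 1, 0, 0))
  expect_equal(weight_variance(4, g), 13)
})

test_that("batch config YAML round-trips all fields", {
  refills <- refill_events(
    timestamp = as.POSIXct("2021-03-05 11:00:00", tz = "UTC") + c(0, 86400 * 4),
    declared_weight = c(6000, NA))
  cfg <- batch_config("demo", data.frame(entry_date = as.Date("2021-03-01"),
                                         n_animals = 600, avg_weight = 30,
                                         age_weeks = 10),
                      data.frame(date = as.Date("2021-06-20"),
                                 n_removed = 100, abattoir_weight = 11000),
                      refills, make_growth(), density_state(640),
                      silo_spec(20))
  p <- tmp_path("batch.yaml")
  write_batch_config(cfg, p)
  cfg2 <- read_batch_config(p)
  expect_equal(cfg2$batch_id, "demo")
  expect_equal(cfg2$entries, cfg$entries)
  expect_equal(cfg2$departures, cfg$departures)
  expect_equal(cfg2$refills$declared_weight, c(6000, NA))
  expect_equal(as.numeric(cfg2$refills$timestamp),
               as.numeric(cfg$refills$timestamp))
  expect_equal(cfg2$growth$var_coeffs, cfg$growth$var_coeffs)
  expect_equal(cfg2$silo$usable_volume, 20)
})

test_that("write_outputs round-trips tables and writes a schema-complete summary", {
  intake <- data.frame(week = 0:9,
                       afi_sensor_kg = cumsum(runif(10, 10, 16)),
                       afi_theory_kg = cumsum(runif(10, 10, 16)),
                       afi_linear_kg = 14.56 * (0:9),
                       n_present = 600)
  intake$deviation <- (intake$afi_sensor_kg - intake$afi_theory_kg) /
    intake$afi_theory_kg
  cleaned <- data.frame(timestamp = as.POSIXct("2021-03-01", tz = "UTC") +
                          7200 * 0:9,
                        weight_kg = seq(11520, 11000, length.out = 10))
  comps <- data.frame(entry_index = 1, week = 9, mean_kg = 70,
                      variance_kg2 = 25, n_alive = 600)
  dist <- merge_and_bin(comps)
  dir <- tmp_path("out")
  write_outputs(list(cleaned = cleaned, intake = intake, distribution = dist,
                     alerts = NULL,
                     summary = list(batch_id = "b1", weeks = 10)), dir)
  wi <- utils::read.csv(file.path(dir, "weekly_intake.csv"))
  expect_equal(wi$afi_sensor_kg, intake$afi_sensor_kg, tolerance = 1e-9)
  expect_equal(wi$week, intake$week)
  cw <- utils::read.csv(file.path(dir, "cleaned_weight.csv"))
  expect_equal(cw$weight_kg, cleaned$weight_kg, tolerance = 1e-9)
  dd <- utils::read.csv(file.path(dir, "distribution.csv"))
  expect_equal(dd$expected_count, dist$bins$expected_count, tolerance = 1e-9)
  smry <- jsonlite::fromJSON(file.path(dir, "summary.json"))
  expect_equal(smry$batch_id, "b1")
  expect_equal(smry$weeks, 10)
})

test_that("an empty distribution writes a header-only CSV", {
  dir <- tmp_path("out")
  write_outputs(list(
    cleaned = data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                         weight_kg = numeric()),
    intake = data.frame(week = integer(), afi_sensor_kg = numeric(),
                        afi_theory_kg = numeric(), afi_linear_kg = numeric(),
                        deviation = numeric()),
    distribution = NULL, alerts = NULL, summary = list(batch_id = "x")), dir)
  dd <- utils::read.csv(file.path(dir, "distribution.csv"))
  expect_equal(nrow(dd), 0)
  expect_named(dd, c("bin_low_kg", "bin_high_kg", "expected_count"))
})
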