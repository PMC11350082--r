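# Instrument-signal processing: closure-flux inversion, sap-flow
# baselining and conversion, in-chamber stem temperature.

test_that("closure-flux inversion recovers the forward-model flux", {
  geom <- chamber_geometry()
  for (f in c(-10, -2, -0.5, -0.1, 0.1, 1, 10)) {
    tr <- one_trace(f, geom)
    est <- compute_closure_flux(tr, geom)
    expect_equal(est$fco2, f, tolerance = 1e-8)
    expect_lt(est$fit_rmse, 1e-9)
  }
})

test_that("flat traces give the steady-state flux", {
  geom <- chamber_geometry()
  t_s <- seq(0, 100, by = 5)
  flat <- function(c_ppm, c_in) {
    data.frame(t_s = t_s, co2_ppm = c_ppm, c_in = c_in,
               chamber_air_temp = 15, pressure = 101.3)
  }
  # at ambient: no flux
  expect_equal(compute_closure_flux(flat(417, 417), geom)$fco2, 0)

  # above ambient: steady state q (C - C_in) / A in molar units, and an
  # elevated chamber concentration means efflux, i.e. negative FCO2
  est <- compute_closure_flux(flat(450, 417), geom)
  q_mol <- geom$flow_closed_lpm / 60 * 101.3 / (8.31446 * 288.15)
  expect_equal(est$fco2, -q_mol * 33 / geom$stem_area_m2, tolerance = 1e-10)
  expect_lt(est$fco2, 0)
})

test_that("degenerate closures are rejected or flagged, not silently used", {
  geom <- chamber_geometry()
  tr <- one_trace(-2, geom)
  expect_error(compute_closure_flux(tr[1:3, ], geom), "insufficient")

  noisy <- tr
  set.seed(1)
  noisy$co2_ppm <- noisy$co2_ppm + rnorm(nrow(noisy), 0, 5)
  est <- compute_closure_flux(noisy, geom, rmse_ceiling = 0.5)
  expect_true(has_flag(est$qc_flag, "CLOSURE_NOISY"))
})

test_that("the initial-slope estimator agrees to leading order", {
  geom <- chamber_geometry()
  tr <- one_trace(-2, geom)
  sl <- compute_closure_flux(tr, geom, estimator = "slope")
  # dilution over the fitted window biases the slope toward zero, but sign
  # and magnitude must be close
  expect_lt(abs(sl$fco2 - (-2)) / 2, 0.25)
  expect_lt(sl$fco2, 0)
})

test_that("batch closure estimation preserves order and timestamps", {
  geom <- chamber_geometry()
  drivers <- manual_drivers(temp = rep(15, 4))
  flux <- data.frame(timestamp = drivers$timestamp,
                     fco2 = c(-3, -1, -0.2, 0.4))
  traces <- generate_closure_traces(flux, geom, drivers)
  est <- compute_closure_fluxes(traces, geom)
  expect_equal(est$timestamp, flux$timestamp)
  expect_equal(est$fco2, flux$fco2, tolerance = 1e-8)
})

test_that("zero-flow baseline averages nightly maxima over seven nights", {
  # 14 nights, dT peaks at 03:00 each night with known nightly maxima
  n_days <- 14
  ts <- seq(as.POSIXct("2021-06-01 00:00:00", tz = "UTC"),
            by = 1800, length.out = n_days * 48)
  hour <- as.integer(format(ts, "%H"))
  drivers <- data.frame(timestamp = ts,
                        ppfd = ifelse(hour >= 4 & hour < 22, 500, 0))
  night_date <- as.Date(ts + 12 * 3600, tz = "UTC")
  maxima <- seq(8, by = 0.5, length.out = length(unique(night_date)))
  names(maxima) <- as.character(unique(night_date))
  dT <- ifelse(hour < 4 | hour >= 22,
               maxima[as.character(night_date)] - abs(hour - 2) * 0.1,
               5)  # depressed daytime dT (flow cools the probe)
  raw <- data.frame(timestamp = ts, dT = unname(dT))
  out <- baseline_zero_flow(raw, drivers, n_nights = 7)
  # an interior day: centered window of 7 nightly maxima
  mid <- format(out$timestamp, "%Y-%m-%d") == "2021-06-08"
  i <- which(as.character(unique(night_date)) == "2021-06-08")
  expect_equal(unique(out$dT0[mid]), mean(maxima[(i - 3):(i + 3)]))
  # baseline never falls below the observed night dT of a zero-flow probe
  expect_true(all(out$dT0 >= 5))
})

test_that("the documented seven-value window mean is reproduced", {
  maxima <- c(8, 9, 10, 11, 12, 11, 10)
  ts <- seq(as.POSIXct("2021-06-01 00:00:00", tz = "UTC"),
            by = 1800, length.out = 7 * 48)
  hour <- as.integer(format(ts, "%H"))
  night_date <- as.Date(ts + 12 * 3600, tz = "UTC")
  di <- match(night_date, unique(night_date))
  drivers <- data.frame(timestamp = ts,
                        ppfd = ifelse(hour >= 4 & hour < 22, 500, 0))
  raw <- data.frame(timestamp = ts,
                    dT = ifelse(hour < 4 | hour >= 22, maxima[di], 4))
  out <- baseline_zero_flow(raw, drivers, n_nights = 7)
  center <- format(out$timestamp, "%Y-%m-%d") == "2021-06-04"
  expect_equal(unique(out$dT0[center]), mean(maxima))
  expect_equal(unique(out$dT0[center]), 10.142857, tolerance = 1e-6)
})

test_that("the baseline ignores daytime probe values entirely", {
  ts <- seq(as.POSIXct("2021-06-01 00:00:00", tz = "UTC"),
            by = 1800, length.out = 7 * 48)
  hour <- as.integer(format(ts, "%H"))
  drivers <- data.frame(timestamp = ts,
                        ppfd = ifelse(hour >= 4 & hour < 22, 500, 0))
  raw1 <- data.frame(timestamp = ts,
                     dT = ifelse(hour < 4 | hour >= 22, 10, 3))
  raw2 <- raw1
  raw2$dT[drivers$ppfd > 0] <- 99  # absurd daytime values
  b1 <- baseline_zero_flow(raw1, drivers)
  b2 <- baseline_zero_flow(raw2, drivers)
  expect_equal(b1$dT0, b2$dT0)
  expect_equal(unique(b1$dT0), 10)
})

test_that("sap flux conversion follows the calibration and clips at zero", {
  raw <- data.frame(timestamp = as.POSIXct("2021-06-01", tz = "UTC") + 1:4,
                    dT = c(10, 8, 11, -1), dT0 = 10)
  out <- granier_sapflux(raw)
  expect_equal(out$j[1], 0)                       # at the baseline
  expect_equal(out$K[2], 0.25)
  expect_equal(out$j[2], 119 * 0.25^1.231)        # direct evaluation
  expect_equal(out$j[3], 0)                       # dT above baseline: clipped
  expect_equal(attr(out, "n_clipped"), 1)
  expect_true(has_flag(out$qc_flag[4], "DT_INVALID"))
  expect_true(is.na(out$j[4]))
})

test_that("sap flux is monotone in the temperature-difference depression", {
  dT <- seq(9.99, 5, length.out = 50)
  raw <- data.frame(timestamp = as.POSIXct("2021-06-01", tz = "UTC") +
                      seq_along(dT),
                    dT = dT, dT0 = 10)
  j <- granier_sapflux(raw)$j
  expect_true(all(diff(j) > 0))
})

test_that("in-chamber stem temperature interpolates the chamber warming", {
  expect_equal(estimate_chamber_stem_temperature(18, 15, 22, k = 0.5), 17)
  expect_equal(estimate_chamber_stem_temperature(18, 15, 18, k = 0.7), 15)
  expect_equal(estimate_chamber_stem_temperature(18, 15, 25, k = 0), 15)
  expect_error(estimate_chamber_stem_temperature(18, 15, 25, k = 1.5),
               "\\[0, 1\\]")
  expect_error(estimate_chamber_stem_temperature(c(1, 2), c(1, 2), 1),
               "misaligned")
})
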