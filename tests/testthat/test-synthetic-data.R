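# Synthetic-data generator: determinism, degenerate configurations, the
# flux algebra of the paired chambers, closure-trace physics, and artifact
# bookkeeping.

test_that("driver generation is reproducible and sized by the date range", {
  cfg <- short_config(seed = 1)
  d1 <- generate_drivers(cfg)
  d2 <- generate_drivers(cfg)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 30 * 48)  # 30 days at 48 half-hours

  d3 <- generate_drivers(short_config(seed = 2))
  expect_false(identical(d1$temp, d3$temp))
})

test_that("zero-amplitude configuration yields constant drivers at the means", {
  cfg <- short_config(temp_seasonal_amp = 0, temp_diurnal_amp = 0,
                      temp_day_sd = 0, ppfd_max = 0, rh_diurnal_amp = 0,
                      rh_day_sd = 0, j_max = 0, co2_diurnal_amp = 0)
  d <- generate_drivers(cfg)
  expect_equal(d$temp, rep(cfg$temp_mean, nrow(d)))
  expect_equal(unique(d$ppfd), 0)
  expect_equal(d$rh, rep(cfg$rh_mean, nrow(d)))
  expect_equal(unique(d$j), 0)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(start = "2021-09-01", end = "2021-06-01"),
               "date range")
  expect_error(sim_config(step_min = 0), "positive")
  expect_error(sim_truth(R0 = -1), "R0")
  expect_error(sim_truth(f = 1.5), "f must")
})

test_that("drivers respect physical ranges and the night structure", {
  d <- generate_drivers(sim_config(seed = 3))
  expect_true(all(d$ppfd >= 0))
  expect_true(all(d$rh >= 0 & d$rh <= 100))
  expect_true(all(d$j >= 0))
  expect_true(!is.unsorted(d$timestamp, strictly = TRUE))
  # sap flow is a daytime hump: the vast majority of dark hours carry no
  # flow (a short evening tail lags the light)
  expect_gt(mean(d$j[d$ppfd == 0] == 0), 0.85)
  expect_equal(mean(d$j[d$ppfd == 0]) / max(d$j), 0, tolerance = 0.05)
  expect_gt(stats::cor(d$ppfd, d$j), 0.7)
})

test_that("generated fluxes obey the component models exactly", {
  truth <- sim_truth(months = 6, R0 = 0.5, b = 0.1, Pmax = 1, f = 0.01,
                     e = 0.02, noise_sd = 0)

  # cold, dark, no-flow conditions: dark flux is -R0
  d0 <- manual_drivers(temp = rep(0, 48))
  fl <- generate_true_fluxes(d0, truth)
  expect_equal(fl$dark$fco2, rep(-0.5, 48))

  # direct evaluation of the temperature response at 10 degC
  d10 <- manual_drivers(temp = rep(10, 48))
  fl <- generate_true_fluxes(d10, truth)
  expect_equal(fl$dark$fco2, rep(-0.5 * exp(1), 48), tolerance = 1e-12)

  # half-saturation identity: f * PPFD = Pmax gives P = Pmax / 2
  dhs <- manual_drivers(temp = rep(0, 48), ppfd = 1 / 0.01)
  fl <- generate_true_fluxes(dhs, truth)
  expect_equal(fl$truth_components$p_true, rep(0.5, 48), tolerance = 1e-12)
})

test_that("a month missing from the truth map is reported by name", {
  truth <- sim_truth(months = 7:9, R0 = 0.5, b = 0.1, Pmax = 1, f = 0.01,
                     e = 0.02)
  d <- manual_drivers(temp = rep(10, 4))  # June
  expect_error(generate_true_fluxes(d, truth), "Jun")
})

test_that("noise-free chamber algebra links the two chambers to P and T", {
  ss <- noiseless_season()
  fl <- ss$fluxes
  tc <- fl$truth_components
  # transparent minus dark recovers the stored photosynthesis everywhere
  expect_equal(fl$transparent$fco2 - fl$dark$fco2, tc$p_true,
               tolerance = 1e-12)
  # dark flux plus stored respiration is the stored transport term
  expect_equal(fl$dark$fco2 + tc$r_prime, tc$t_true, tolerance = 1e-12)
})

test_that("flux noise is reproducible under a fixed seed", {
  truth <- sim_truth(noise_sd = 0.1)
  d <- generate_drivers(short_config())
  f1 <- generate_true_fluxes(d, truth, seed = 42)
  f2 <- generate_true_fluxes(d, truth, seed = 42)
  expect_identical(f1$dark$fco2, f2$dark$fco2)
  f3 <- generate_true_fluxes(d, truth, seed = 43)
  expect_false(identical(f1$dark$fco2, f3$dark$fco2))
})

test_that("closure traces follow the chamber ODE", {
  skip_if_not_installed("deSolve")
  geom <- chamber_geometry()
  for (f in c(-5, -0.5, 0.3)) {
    tr <- one_trace(f, geom)
    # independent oracle: numeric integration of the mass balance
    k <- geom$flow_closed_lpm / 60 / geom$volume_l
    q_mol <- geom$flow_closed_lpm / 60 * 101.3 / (8.31446 * (15 + 273.15))
    src <- (-f) * geom$stem_area_m2 / q_mol * k  # ppm/s at equilibrium scale
    ode <- deSolve::lsoda(c(C = tr$c_in[1]), times = tr$t_s,
                          func = function(t, y, p) {
                            list(src + k * (tr$c_in[1] - y))
                          }, parms = NULL, rtol = 1e-12, atol = 1e-12)
    expect_equal(tr$co2_ppm, unname(ode[, "C"]), tolerance = 1e-9)
  }
})

test_that("closure traces start at ambient and tend to the steady state", {
  geom <- chamber_geometry()
  tr <- one_trace(-2, geom)
  expect_equal(nrow(tr), 21)  # 100 s closure sampled every 5 s
  expect_equal(tr$co2_ppm[1], tr$c_in[1])
  # stem efflux (negative flux) raises the chamber concentration
  expect_true(all(diff(tr$co2_ppm) > 0))
  q_mol <- geom$flow_closed_lpm / 60 * 101.3 / (8.31446 * (15 + 273.15))
  c_eq <- tr$c_in[1] + 2 * geom$stem_area_m2 / q_mol
  expect_true(all(tr$co2_ppm <= c_eq + 1e-9))

  # zero flux at ambient inflow: the trace never moves
  tr0 <- one_trace(0, geom)
  expect_equal(tr0$co2_ppm, rep(tr0$c_in[1], 21))
})

test_that("artifact injection logs exactly what it plants", {
  ss <- noiseless_season()
  fl <- ss$fluxes

  none <- inject_artifacts(fl$dark, fl$transparent, ss$drivers,
                           n_spikes = 0, rh_fraction = 0, gap_fraction = 0)
  expect_identical(none$dark, fl$dark)
  expect_identical(none$drivers, ss$drivers)
  expect_equal(nrow(none$log), 0)

  art <- inject_artifacts(fl$dark, fl$transparent, ss$drivers,
                          n_spikes = 5, rh_fraction = 0.2,
                          gap_fraction = 0.01, seed = 7)
  expect_equal(sum(art$log$type == "spike"), 5)
  expect_equal(sum(art$log$type == "high_rh"),
               round(0.2 * nrow(ss$drivers)))
  expect_equal(nrow(art$dark), nrow(fl$dark) - sum(art$log$type == "gap"))
  expect_true(all(art$drivers$rh[art$drivers$timestamp %in%
                                   art$log$timestamp[art$log$type == "high_rh"]] == 90))

  expect_error(inject_artifacts(fl$dark, fl$transparent, ss$drivers,
                                rh_fraction = 1.2), "fraction")
})
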