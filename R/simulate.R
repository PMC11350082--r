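# Synthetic-data generator: boreal growing-season drivers, true process
# fluxes obeying the three component models with monthly parameters, noisy
# paired-chamber observations, chamber closure traces, and QC artifacts.
# Ground truth is retained throughout so the full pipeline can be scored
# against it.

#' Ground-truth process parameters for simulation
#'
#' Defines the per-month parameters of the three flux components: stem
#' respiration `R' = R0 * exp(b * temp)`, bark photosynthesis
#' `P = Pmax * f * PPFD / (f * PPFD + Pmax)`, and the sap-transport term
#' `T = e * J`. Defaults emulate the seasonal courses typical of a boreal
#' Scots pine stem: basal respiration `R0` declining over the season within
#' 0.3-0.8 umol m-2 s-1, temperature sensitivity `b` rising towards autumn,
#' light-saturated photosynthesis `Pmax` and quantum yield `f` declining
#' after midsummer, and the transport slope `e` decreasing as the axial
#' CO2 gradient weakens.
#'
#' @param months integer months covered (default June-September).
#' @param R0 stem respiration at 0 degC, umol m-2 s-1 (one per month).
#' @param b temperature sensitivity, 1/degC (Q10 = exp(10 b)).
#' @param Pmax light-saturation point, umol m-2 s-1.
#' @param f quantum yield, umol CO2 per umol quanta.
#' @param e transport slope, umol m-2 s-1 per unit sap flux density.
#' @param noise_sd additive Gaussian measurement noise on each chamber
#'   flux, umol m-2 s-1.
#' @return an object of class `sim_truth`: list with elements `params`
#'   (data.frame month, R0, b, Pmax, f, e) and `noise_sd`.
#' @export
sim_truth <- function(months = 6:9,
                      R0   = c(0.80, 0.65, 0.50, 0.35),
                      b    = c(0.080, 0.090, 0.100, 0.115),
                      Pmax = c(1.40, 1.20, 0.90, 0.60),
                      f    = c(0.015, 0.012, 0.009, 0.006),
                      e    = c(0.012, 0.010, 0.008, 0.006),
                      noise_sd = 0.1) {
  n <- length(months)
  rec <- function(x) rep_len(x, n)
  params <- data.frame(month = as.integer(months), R0 = rec(R0), b = rec(b),
                       Pmax = rec(Pmax), f = rec(f), e = rec(e))
  if (any(params$R0 <= 0)) stop("R0 must be > 0")
  if (any(params$b <= 0)) stop("b must be > 0")
  if (any(params$Pmax <= 0)) stop("Pmax must be > 0")
  if (any(params$f <= 0 | params$f >= 1)) stop("f must be in (0, 1)")
  if (any(params$e < 0)) stop("e must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(params = params, noise_sd = noise_sd), class = "sim_truth")
}

#' Configuration for the driver simulator
#'
#' Describes the boreal June-September measurement conditions emulated by
#' [generate_drivers()]: diurnal and seasonal courses of xylem temperature,
#' above-canopy photosynthetic photon flux density from a solar-elevation
#' model at the site latitude, relative humidity anti-correlated with
#' temperature, and a daytime sap-flow hump tracking light with a lag.
#'
#' Sap flux below `j_floor` is reported as exactly zero: thermal-dissipation
#' probes cannot resolve flows below their detection limit (the probe
#' temperature difference reaches the zero-flow baseline and the flow index
#' is clipped at zero), so near-zero night-time flows read as zeros.
#'
#' @param start,end first and last calendar day (parsed as UTC dates).
#' @param step_min sampling interval in minutes (the 30-min chamber cycle).
#' @param lat site latitude in decimal degrees, used by the solar model.
#' @param seed integer seed for the day-to-day weather variability.
#' @param temp_mean season-mean xylem temperature, degC.
#' @param temp_seasonal_amp amplitude of the seasonal temperature course.
#' @param temp_diurnal_amp amplitude of the diurnal course (peak mid-afternoon).
#' @param temp_day_sd sd of the random day-to-day temperature offset.
#' @param ppfd_max clear-sky PPFD at solar elevation 90 deg, umol m-2 s-1.
#' @param clearness_range range of the daily clearness factor (uniform draw).
#' @param rh_mean,rh_diurnal_amp,rh_day_sd relative humidity course, percent.
#' @param j_max seasonal maximum sap flux density (pipeline J unit
#'   convention, g m-2 h-1).
#' @param j_floor sap-probe detection floor; computed J below this reads 0.
#' @param j_lag_h lag of the sap-flow hump behind solar elevation, hours.
#' @param co2_ambient mean ambient CO2, ppm.
#' @param co2_diurnal_amp diurnal CO2 amplitude, ppm.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(start = "2021-06-01", end = "2021-09-30",
                       step_min = 30, lat = 61.85, seed = 1L,
                       temp_mean = 12, temp_seasonal_amp = 5,
                       temp_diurnal_amp = 4, temp_day_sd = 1.5,
                       ppfd_max = 1600, clearness_range = c(0.4, 1),
                       rh_mean = 65, rh_diurnal_amp = 15, rh_day_sd = 4,
                       j_max = 100, j_floor = 5, j_lag_h = 1.5,
                       co2_ambient = 417, co2_diurnal_amp = 5) {
  start_d <- as.Date(start)
  end_d <- as.Date(end)
  if (is.na(start_d) || is.na(end_d) || end_d < start_d) {
    stop("invalid date range: `end` must not precede `start`")
  }
  if (!is.numeric(step_min) || step_min <= 0) {
    stop("`step_min` must be a positive number of minutes")
  }
  structure(list(start = start_d, end = end_d, step_min = step_min,
                 lat = lat, seed = as.integer(seed),
                 temp_mean = temp_mean, temp_seasonal_amp = temp_seasonal_amp,
                 temp_diurnal_amp = temp_diurnal_amp, temp_day_sd = temp_day_sd,
                 ppfd_max = ppfd_max, clearness_range = clearness_range,
                 rh_mean = rh_mean, rh_diurnal_amp = rh_diurnal_amp,
                 rh_day_sd = rh_day_sd,
                 j_max = j_max, j_floor = j_floor, j_lag_h = j_lag_h,
                 co2_ambient = co2_ambient, co2_diurnal_amp = co2_diurnal_amp),
            class = "sim_config")
}

# sine of solar elevation from day-of-year, fractional hour and latitude
sin_solar_elevation <- function(doy, hour, lat_deg) {
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat <- lat_deg * pi / 180
  sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(pi / 12 * (hour - 12))
}

#' Generate a gap-free environmental driver series
#'
#' Produces the half-hourly (configurable) driver grid used by the flux
#' simulator: xylem temperature with seasonal, diurnal (mid-afternoon peak)
#' and random day-to-day components; PPFD from a solar-elevation model with
#' a per-day clearness factor (zero at night); relative humidity peaking at
#' night; sap flux density as a daytime hump lagging solar elevation with a
#' detection floor (exact zeros at night); and ambient CO2.
#' Bit-reproducible for a fixed `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `timestamp` (POSIXct UTC), `temp` (degC),
#'   `ppfd` (umol m-2 s-1), `rh` (percent), `j` (sap flux density) and
#'   `co2_ambient` (ppm).
#' @export
generate_drivers <- function(config) {
  if (!inherits(config, "sim_config")) stop("`config` must be a sim_config")
  step_s <- config$step_min * 60
  t0 <- as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$end, "23:59:59"), tz = "UTC")
  ts <- seq(t0, t1, by = step_s)

  lt <- as.POSIXlt(ts)
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60 + lt$sec / 3600
  day_idx <- as.integer(as.Date(ts, tz = "UTC") - config$start) + 1L
  n_days <- max(day_idx)

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(config$seed)
  clear <- stats::runif(n_days, config$clearness_range[1],
                        config$clearness_range[2])
  temp_off <- stats::rnorm(n_days, 0, config$temp_day_sd)
  rh_off <- stats::rnorm(n_days, 0, config$rh_day_sd)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  diurnal <- cos(2 * pi * (hour - 15.5) / 24)  # peak 15:30, trough 03:30
  temp <- config$temp_mean +
    config$temp_seasonal_amp * cos(2 * pi * (doy - 200) / 365) +
    config$temp_diurnal_amp * diurnal + temp_off[day_idx]

  sinel <- sin_solar_elevation(doy, hour, config$lat)
  ppfd <- config$ppfd_max * clear[day_idx] * pmax(0, sinel)

  rh <- clamp(config$rh_mean - config$rh_diurnal_amp * diurnal +
                rh_off[day_idx], 5, 100)

  # sap flow: daytime hump correlated with light, lagged, peaking mid-season
  sinel_lag <- sin_solar_elevation(doy, hour - config$j_lag_h, config$lat)
  season_j <- 0.6 + 0.4 * cos(2 * pi * (doy - 195) / 365)
  j <- config$j_max * clear[day_idx] * season_j * pmax(0, sinel_lag)^1.3
  j[j < config$j_floor] <- 0

  co2 <- config$co2_ambient +
    config$co2_diurnal_amp * cos(2 * pi * (hour - 4) / 24)

  data.frame(timestamp = ts, temp = temp, ppfd = ppfd, rh = rh, j = j,
             co2_ambient = co2)
}

# model kernels shared by the generator and the fitting side
resp_model <- function(R0, b, temp) R0 * exp(b * temp)
photo_model <- function(Pmax, f, ppfd) Pmax * f * ppfd / (f * ppfd + Pmax)
transport_model <- function(e, j) e * j

#' Simulate paired-chamber flux observations with known ground truth
#'
#' Evaluates the three process models at each driver timestamp using the
#' month's true parameters and assembles the two chamber series under the
#' efflux-negative sign convention: the dark chamber sees `-R' + T`
#' (photosynthesis absent without light), the transparent chamber
#' `-R' + P + T`. Independent Gaussian measurement noise of sd
#' `truth$noise_sd` is added per chamber; the stored truth components are
#' noise-free.
#'
#' @param drivers a driver data.frame from [generate_drivers()].
#' @param truth a [sim_truth()] object whose months cover the drivers.
#' @param tree_id tree label attached to the records.
#' @param seed optional integer seed for the noise draw (restores the RNG
#'   state afterwards); if `NULL` the current RNG stream is used.
#' @return list with elements `dark` and `transparent` (data.frames
#'   `timestamp`, `chamber_type`, `tree_id`, `fco2`, `qc_flag`, `month`) and
#'   `truth_components` (`timestamp`, `r_prime`, `p_true`, `t_true`).
#' @export
generate_true_fluxes <- function(drivers, truth, tree_id = "A", seed = NULL) {
  if (!inherits(truth, "sim_truth")) stop("`truth` must be a sim_truth")
  mon <- flux_month(drivers$timestamp)
  idx <- match(mon, truth$params$month)
  if (anyNA(idx)) {
    bad <- sort(unique(mon[is.na(idx)]))
    stop(sprintf("no truth parameters for month(s): %s",
                 paste(month.abb[bad], collapse = ", ")))
  }
  pp <- truth$params[idx, ]
  r_prime <- resp_model(pp$R0, pp$b, drivers$temp)
  p_true <- photo_model(pp$Pmax, pp$f, drivers$ppfd)
  t_true <- transport_model(pp$e, drivers$j)

  n <- nrow(drivers)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
  }
  eps_d <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else 0
  eps_t <- if (truth$noise_sd > 0) stats::rnorm(n, 0, truth$noise_sd) else 0

  rec <- function(type, fco2) {
    data.frame(timestamp = drivers$timestamp, chamber_type = type,
               tree_id = tree_id, fco2 = fco2, qc_flag = "", month = mon,
               stringsAsFactors = FALSE)
  }
  list(dark = rec("dark", -r_prime + t_true + eps_d),
       transparent = rec("transparent", -r_prime + p_true + t_true + eps_t),
       truth_components = data.frame(timestamp = drivers$timestamp,
                                     r_prime = r_prime, p_true = p_true,
                                     t_true = t_true))
}

#' Synthesize chamber closure concentration traces
#'
#' For each flux record, solves the flow-through chamber mass balance
#' `V dC/dt = S A + q (C_in - C)` with chamber-frame source `S = -FCO2`
#' (stem efflux, negative FCO2, raises chamber concentration) forward from
#' `C(0) = C_in`, sampling the exact solution
#' `C(t) = C_eq + (C0 - C_eq) exp(-q t / V)` every `sample_dt` seconds over
#' the closure. The molar conversion between surface flux and mixing ratio
#' uses the ideal gas law at the recorded chamber temperature and pressure,
#' so the inversion in [compute_closure_flux()] is exact.
#'
#' @param flux a flux record data.frame (one chamber).
#' @param geom a [chamber_geometry()].
#' @param drivers driver series supplying ambient CO2 and air temperature
#'   at each record's timestamp.
#' @param pressure_kpa chamber air pressure, kPa.
#' @return long data.frame: `closure_id`, `timestamp`, `t_s`, `co2_ppm`,
#'   `c_in`, `chamber_air_temp`, `pressure`.
#' @export
generate_closure_traces <- function(flux, geom, drivers,
                                    pressure_kpa = 101.3) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (any(!is.finite(flux$fco2))) stop("flux values must be finite")
  di <- match(flux$timestamp, drivers$timestamp)
  if (anyNA(di)) stop("every flux record needs a matching driver timestamp")
  c_in <- drivers$co2_ambient[di]
  airt <- drivers$temp[di]

  t_s <- seq(0, geom$closure_len_s, by = geom$sample_dt_s)
  n_s <- length(t_s)
  n_r <- nrow(flux)

  k <- geom$flow_closed_lpm / 60 / geom$volume_l              # 1/s
  q_mol <- geom$flow_closed_lpm / 60 *
    mol_per_liter(airt, pressure_kpa)                         # mol air / s
  c_eq <- c_in + (-flux$fco2) * geom$stem_area_m2 / q_mol     # ppm

  co2 <- rep(c_eq, each = n_s) +
    rep(c_in - c_eq, each = n_s) * exp(-k * rep(t_s, times = n_r))
  data.frame(closure_id = rep(seq_len(n_r), each = n_s),
             timestamp = rep(flux$timestamp, each = n_s),
             t_s = rep(t_s, times = n_r), co2_ppm = co2,
             c_in = rep(c_in, each = n_s),
             chamber_air_temp = rep(airt, each = n_s),
             pressure = pressure_kpa)
}

#' Plant known QC artifacts into simulated data
#'
#' Adds spike outliers to chamber fluxes, raises relative humidity above the
#' condensation threshold in chosen windows, and deletes records to create
#' gaps. Every planted artifact is logged so downstream filter tests can
#' assert exact bookkeeping.
#'
#' @param dark,transparent chamber flux data.frames.
#' @param drivers driver data.frame.
#' @param n_spikes number of spike outliers to plant (split at random
#'   between the chambers).
#' @param spike_sd_mult spike magnitude in multiples of the chamber series'
#'   standard deviation.
#' @param rh_fraction fraction of driver rows whose RH is raised to
#'   `rh_value`.
#' @param rh_value RH assigned to the chosen windows, percent.
#' @param gap_fraction fraction of timestamps removed from both chambers.
#' @param seed integer seed for artifact placement.
#' @return list `dark`, `transparent`, `drivers`, `log` (data.frame with
#'   columns `type`, `timestamp`, `chamber`).
#' @export
inject_artifacts <- function(dark, transparent, drivers,
                             n_spikes = 5, spike_sd_mult = 10,
                             rh_fraction = 0.2, rh_value = 90,
                             gap_fraction = 0, seed = 1L) {
  if (rh_fraction > 1 || gap_fraction > 1) {
    stop("artifact fractions must not exceed 1")
  }
  log <- data.frame(type = character(), timestamp = as.POSIXct(character()),
                    chamber = character(), stringsAsFactors = FALSE)
  if (n_spikes == 0 && rh_fraction == 0 && gap_fraction == 0) {
    return(list(dark = dark, transparent = transparent, drivers = drivers,
                log = log))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  if (n_spikes > 0) {
    chamber <- sample(c("dark", "transparent"), n_spikes, replace = TRUE)
    for (ch in c("dark", "transparent")) {
      k <- sum(chamber == ch)
      if (k == 0) next
      df <- if (ch == "dark") dark else transparent
      rows <- sample(nrow(df), k)
      mag <- spike_sd_mult * stats::sd(df$fco2)
      df$fco2[rows] <- df$fco2[rows] + sample(c(-1, 1), k, replace = TRUE) * mag
      if (ch == "dark") dark <- df else transparent <- df
      log <- rbind(log, data.frame(type = "spike",
                                   timestamp = df$timestamp[rows],
                                   chamber = ch, stringsAsFactors = FALSE))
    }
  }
  if (rh_fraction > 0) {
    k <- round(rh_fraction * nrow(drivers))
    rows <- sample(nrow(drivers), k)
    drivers$rh[rows] <- rh_value
    log <- rbind(log, data.frame(type = "high_rh",
                                 timestamp = drivers$timestamp[rows],
                                 chamber = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  if (gap_fraction > 0) {
    k <- round(gap_fraction * nrow(dark))
    rows <- sample(nrow(dark), k)
    gap_ts <- dark$timestamp[rows]
    dark <- dark[!dark$timestamp %in% gap_ts, ]
    transparent <- transparent[!transparent$timestamp %in% gap_ts, ]
    log <- rbind(log, data.frame(type = "gap", timestamp = gap_ts,
                                 chamber = NA_character_,
                                 stringsAsFactors = FALSE))
  }
  list(dark = dark, transparent = transparent, drivers = drivers, log = log)
}
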