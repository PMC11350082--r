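# Shared fixtures: all synthetic, built in code at test time.

# short single-month season, quick to fit
short_config <- function(...) {
  sim_config(start = "2021-06-01", end = "2021-06-30", ...)
}

# drivers with hand-set values on a regular 30-min June grid
manual_drivers <- function(temp, ppfd = 0, rh = 60, j = 0, co2 = 417) {
  n <- max(length(temp), length(ppfd), length(rh), length(j))
  ts <- seq(as.POSIXct("2021-06-01 00:00:00", tz = "UTC"),
            by = 1800, length.out = n)
  data.frame(timestamp = ts,
             temp = rep_len(temp, n), ppfd = rep_len(ppfd, n),
             rh = rep_len(rh, n), j = rep_len(j, n),
             co2_ambient = rep_len(co2, n))
}

# full-season noiseless aligned table plus its generating truth
noiseless_season <- function(seed = 1) {
  truth <- sim_truth(noise_sd = 0)
  drivers <- generate_drivers(sim_config(seed = seed))
  fl <- generate_true_fluxes(drivers, truth)
  list(truth = truth, drivers = drivers, fluxes = fl,
       aligned = align_chambers(fl$dark, fl$transparent, drivers))
}

# single synthetic closure trace for a known surface flux
one_trace <- function(fco2, geom = chamber_geometry(), c_in = 417,
                      temp = 15, pressure = 101.3) {
  flux <- data.frame(timestamp = as.POSIXct("2021-06-01 12:00:00",
                                            tz = "UTC"),
                     fco2 = fco2)
  drivers <- data.frame(timestamp = flux$timestamp, temp = temp,
                        co2_ambient = c_in)
  generate_closure_traces(flux, geom, drivers, pressure_kpa = pressure)
}
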