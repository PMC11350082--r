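#!/usr/bin/env Rscript
# Stage 1 — simulate a boreal June-September measurement season.
#
# Generates half-hourly environmental drivers (xylem temperature, PPFD,
# relative humidity, sap flux density, ambient CO2) for one tree, the true
# process fluxes under the known monthly parameters, and the noisy paired
# dark/transparent chamber observations. Ground truth is written alongside
# so later stages can be scored against it.

library(stemflux)

seed <- 1L
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

truth <- sim_truth(noise_sd = 0.1)
cfg <- sim_config(seed = seed)
drivers <- generate_drivers(cfg)
fl <- generate_true_fluxes(drivers, truth, seed = seed)

dr <- drivers
names(dr) <- c("timestamp", "temp_c", "ppfd", "rh_pct", "sapflux_g_m2_h",
               "co2_ambient_ppm")
write_timeseries(dr, file.path(out, "drivers.csv"))
write_timeseries(fl$dark[, c("timestamp", "fco2", "qc_flag")],
                 file.path(out, "flux_dark.csv"))
write_timeseries(fl$transparent[, c("timestamp", "fco2", "qc_flag")],
                 file.path(out, "flux_transparent.csv"))
write_timeseries(fl$truth_components, file.path(out, "truth.csv"))
jsonlite::write_json(list(params = truth$params, noise_sd = truth$noise_sd,
                          seed = seed),
                     file.path(out, "truth_params.json"),
                     auto_unbox = TRUE, pretty = TRUE, digits = NA)

cat(sprintf("simulated %d half-hourly records over %s .. %s\n",
            nrow(drivers), cfg$start, cfg$end))
cat(sprintf("seasonal maxima: PPFD %.0f umol m-2 s-1, J %.1f, temp %.1f C\n",
            max(drivers$ppfd), max(drivers$j), max(drivers$temp)))
cat(sprintf("night shares: PPFD==0 %.0f%%, J==0 %.0f%%\n",
            100 * mean(drivers$ppfd == 0), 100 * mean(drivers$j == 0)))
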