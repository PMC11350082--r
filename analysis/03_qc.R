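#!/usr/bin/env Rscript
# Stage 3 — quality control and chamber alignment.
#
# Plants known artifacts (spikes, high-humidity windows, gaps) into the
# simulated season, applies the flag-based filters (technical check, 3-SD
# outlier rule, RH > 85% removal), and assembles the aligned analysis
# table, reporting how much data each filter removed.

library(stemflux)

seed <- 1L
out <- "results/03_qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

drivers <- read_timeseries("results/01_simulate/drivers.csv")
names(drivers) <- c("timestamp", "temp", "ppfd", "rh", "j", "co2_ambient")
dark <- read_timeseries("results/01_simulate/flux_dark.csv")
transparent <- read_timeseries("results/01_simulate/flux_transparent.csv")
dark$tree_id <- "A"; dark$chamber_type <- "dark"
transparent$tree_id <- "A"; transparent$chamber_type <- "transparent"

art <- inject_artifacts(dark, transparent, drivers, n_spikes = 5,
                        rh_fraction = 0.1, gap_fraction = 0.02, seed = seed)
cat(sprintf("planted artifacts: %d spikes, %d high-RH windows, %d gaps\n",
            sum(art$log$type == "spike"), sum(art$log$type == "high_rh"),
            sum(art$log$type == "gap")))

run_qc <- function(rec) {
  rec <- technical_qc(rec)
  rec <- filter_outliers_3sd(rec)
  filter_high_rh(rec, art$drivers)
}
dark_q <- run_qc(art$dark)
transp_q <- run_qc(art$transparent)

for (nm in c("dark", "transparent")) {
  ct <- qc_counts(if (nm == "dark") dark_q else transp_q)
  cat(sprintf("%s chamber: %d records, %d flagged (%.1f%% removed)\n",
              nm, ct$n_total, ct$n_flagged, 100 * ct$n_flagged / ct$n_total))
}

aligned <- align_chambers(dark_q, transp_q, art$drivers)
qa <- attr(aligned, "qc_counts")
cat(sprintf("aligned table: %d matched, %d dropped by flags, %d rows out\n",
            qa$n_matched, qa$n_flagged, qa$n_out))

low <- select_low_sapflow(aligned)
cat("low-sap-flow respiration subset per month:\n")
print(attr(low, "n_retained"))

write_timeseries(aligned, file.path(out, "aligned.csv"))
jsonlite::write_json(list(dark = qc_counts(dark_q),
                          transparent = qc_counts(transp_q),
                          alignment = qa),
                     file.path(out, "qc_report.json"),
                     auto_unbox = TRUE, pretty = TRUE)
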