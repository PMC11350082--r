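#!/usr/bin/env Rscript
# Stage 5 — validation and summaries.
#
# Validates the parameterization by the 8:2 train/test scheme (components
# refitted on the training split, reconstruction -R' + P' + T' regressed
# against the held-out measured transparent flux), and summarizes the
# season: hourly diurnal means per month and monthly contribution fractions
# of respiration, photosynthesis and transport in both normalizations.

library(stemflux)

seed <- 1L
out <- "results/05_evaluate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

aligned <- read_timeseries("results/03_qc/aligned.csv")

sp <- train_test_split(aligned, ratio = 0.8, seed = seed)
part_train <- fit_stem_partition(sp$train)
val <- validate_reconstruction(sp$test, part_train$params)
write.csv(val, file.path(out, "validation.csv"), row.names = FALSE)
cat("held-out reconstruction (measured ~ -R' + P' + T'):\n")
print(val, digits = 4)

part <- fit_stem_partition(aligned)
dm <- diurnal_means(part$components)
write.csv(dm, file.path(out, "diurnal_means.csv"), row.names = FALSE)
rflux <- dm[dm$variable == "r_flux", ]
peak <- do.call(rbind, lapply(split(rflux, rflux$month), function(d)
  data.frame(month = d$month[1], peak_hour = d$hour[which.min(d$mean)])))
cat("\nhour of maximum respiration (most negative respiratory flux):\n")
print(peak, row.names = FALSE)

for (form in c("mean_of_components", "per_row")) {
  ct <- monthly_contributions(part$components, form = form)
  write.csv(ct, file.path(out, paste0("contributions_", form, ".csv")),
            row.names = FALSE)
}
ct <- monthly_contributions(part$components)
cat("\nmonthly shares of |R'|, |P|, |T| (sum = 100%):\n")
print(data.frame(month = month.abb[ct$month],
                 respiration = round(ct$share_r, 1),
                 photosynthesis = round(ct$share_p, 1),
                 transport = round(ct$share_t, 1)), row.names = FALSE)
cat(sprintf("\nratio-form conservation: max |sum - 1| = %.1e\n",
            max(abs(ct$ratio_r + ct$ratio_p + ct$ratio_t - 1))))
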