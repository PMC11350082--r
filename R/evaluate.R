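# Validation and reporting: train/test reconstruction check, diurnal hourly
# means, monthly contribution accounting in both normalizations, and
# parameter-recovery scoring against simulation ground truth.

#' Random train/test partition of an aligned table
#'
#' Uniform random split without replacement, by default stratified by
#' calendar month so every month appears in both sets. Within each stratum
#' the training set takes `ceiling(ratio * n)` rows.
#'
#' @param table data.frame to split.
#' @param ratio training fraction in (0, 1); default 0.8 (the 8:2 scheme).
#' @param seed integer seed making the partition reproducible.
#' @param stratify_by column name to stratify on, or `NULL` for a plain
#'   split.
#' @return list with elements `train` and `test`.
#' @export
train_test_split <- function(table, ratio = 0.8, seed = 1L,
                             stratify_by = "month") {
  if (ratio <= 0 || ratio >= 1) stop("`ratio` must lie strictly in (0, 1)")
  n <- nrow(table)
  if (n < 10) stop("need at least 10 rows to split")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  strata <- if (is.null(stratify_by)) rep(1L, n) else table[[stratify_by]]
  train_idx <- unlist(lapply(split(seq_len(n), strata), function(idx) {
    k <- ceiling(ratio * length(idx))
    sample(idx, k)
  }), use.names = FALSE)
  train_idx <- sort(train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[-train_idx, , drop = FALSE])
}

#' Validate the partitioning by reconstruction on held-out data
#'
#' Sums the three parameterized components `-R' + P' + T'` on test rows
#' using parameters fitted on training data only, and regresses the
#' measured transparent-chamber flux on the reconstruction. Reports slope,
#' intercept, R-squared (squared Pearson correlation of measured vs
#' predicted), residual standard error and test size per month and pooled.
#'
#' @param test held-out aligned-table rows.
#' @param params monthly parameter table (fitted on the training set).
#' @return data.frame: `month` (`"all"` for pooled), `slope`, `intercept`,
#'   `r_squared`, `rse`, `n_test`.
#' @export
validate_reconstruction <- function(test, params) {
  pred_all <- predict_components(params, test)
  predicted <- -pred_all$r_prime + pred_all$p_model + pred_all$t_model
  one <- function(meas, pred, label) {
    n <- length(meas)
    if (n < 2) {
      warning(sprintf("month %s has fewer than 2 test rows; skipped", label))
      return(NULL)
    }
    fit <- stats::lm(meas ~ pred)
    r2 <- stats::cor(meas, pred)^2
    data.frame(month = label,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2,
               rse = sqrt(sum(stats::resid(fit)^2) / (n - 2)),
               n_test = n, stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in sort(unique(test$month))) {
    rows <- test$month == m
    out[[length(out) + 1L]] <- one(test$tfco2[rows], predicted[rows],
                                   month.abb[m])
  }
  out[[length(out) + 1L]] <- one(test$tfco2, predicted, "all")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hourly diurnal means of the flux components
#'
#' Averages each component per hour of day within each month: the
#' respiratory flux `-R'`, measured and modeled photosynthesis and
#' transport, and the two measured chamber fluxes. Empty hour cells are
#' missing, not zero; per-cell counts are attached.
#'
#' @param components the `components` data.frame of a
#'   [fit_stem_partition()] result (or any frame with `timestamp`, `month`
#'   and the component columns).
#' @param vars component columns to average.
#' @return long data.frame: `month`, `hour`, `variable`, `mean`, `n`.
#' @export
diurnal_means <- function(components,
                          vars = c("r_flux", "p_meas", "p_model", "t_resid",
                                   "t_model", "tfco2", "dfco2")) {
  df <- components
  if (!"r_flux" %in% names(df) && "r_prime" %in% names(df)) {
    df$r_flux <- -df$r_prime  # respiratory flux, efflux-negative
  }
  vars <- intersect(vars, names(df))
  hour <- flux_hour(df$timestamp)
  key <- interaction(df$month, hour, drop = FALSE)
  out <- list()
  for (v in vars) {
    mu <- tapply(df[[v]], key, function(x) {
      x <- x[is.finite(x)]
      if (length(x)) mean(x) else NA_real_
    })
    nn <- tapply(df[[v]], key, function(x) sum(is.finite(x)))
    nn[is.na(nn)] <- 0L  # hour cells with no rows stay present, mean NA
    parts <- do.call(rbind, strsplit(names(mu), ".", fixed = TRUE))
    out[[v]] <- data.frame(month = as.integer(parts[, 1]),
                           hour = as.integer(parts[, 2]),
                           variable = v, mean = as.numeric(mu),
                           n = as.integer(nn), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$variable, res$month, res$hour), ]
  rownames(res) <- NULL
  res
}

#' Monthly contribution of each component to the net flux
#'
#' Two normalizations of the monthly component accounting, both conserved
#' by construction:
#' * ratio form: `-R'/FCO2 + P/FCO2 + T/FCO2 = 1` (FCO2 is the transparent
#'   chamber flux, negative for net efflux), and
#' * share form: `|R'|, |P|, |T|` as percentages of their summed absolute
#'   values (total set to 100%).
#'
#' By default ratios are formed from monthly means of the components
#' divided by the monthly mean flux (`"mean_of_components"`): averaging
#' per-row ratios explodes when FCO2 crosses zero. Per-row averaging is
#' available as `form = "per_row"` for comparison; both conserve exactly.
#' Rows where any component is undefined (night-time P) are excluded so the
#' accounting identity holds on the rows actually summarized.
#'
#' @param components the `components` data.frame of a
#'   [fit_stem_partition()] result.
#' @param form `"mean_of_components"` (default) or `"per_row"`.
#' @return data.frame per month: `tree_id`, `month`, `ratio_r`, `ratio_p`,
#'   `ratio_t`, `share_r`, `share_p`, `share_t`, `n`, `flagged` (TRUE when
#'   the monthly mean flux is ~0 and the ratio form is undefined).
#' @export
monthly_contributions <- function(components,
                                  form = c("mean_of_components", "per_row")) {
  form <- match.arg(form)
  ok <- is.finite(components$r_prime) & is.finite(components$p_meas) &
    is.finite(components$t_resid) & is.finite(components$tfco2)
  df <- components[ok, ]
  out <- list()
  for (m in sort(unique(df$month))) {
    d <- df[df$month == m, ]
    n <- nrow(d)
    if (form == "mean_of_components") {
      mr <- mean(d$r_prime); mp <- mean(d$p_meas); mt <- mean(d$t_resid)
      mf <- mean(d$tfco2)
      flagged <- abs(mf) < 1e-12
      ratio <- if (flagged) rep(NA_real_, 3) else c(-mr, mp, mt) / mf
      tot <- abs(mr) + abs(mp) + abs(mt)
      share <- 100 * c(abs(mr), abs(mp), abs(mt)) / tot
    } else {
      nz <- abs(d$tfco2) > 1e-12
      flagged <- !any(nz)
      ratio <- c(mean(-d$r_prime[nz] / d$tfco2[nz]),
                 mean(d$p_meas[nz] / d$tfco2[nz]),
                 mean(d$t_resid[nz] / d$tfco2[nz]))
      tot <- abs(d$r_prime) + abs(d$p_meas) + abs(d$t_resid)
      share <- 100 * c(mean(abs(d$r_prime) / tot), mean(abs(d$p_meas) / tot),
                       mean(abs(d$t_resid) / tot))
    }
    out[[length(out) + 1L]] <- data.frame(
      tree_id = d$tree_id[1], month = m,
      ratio_r = ratio[1], ratio_p = ratio[2], ratio_t = ratio[3],
      share_r = share[1], share_p = share[2], share_t = share[3],
      n = n, flagged = flagged, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Score recovered parameters against simulation ground truth
#'
#' Joins a fitted monthly parameter table with the generator's true
#' parameters and reports, per parameter x month: bias (estimate - truth),
#' relative error, and whether the truth lies inside the fitted 95%
#' confidence interval.
#'
#' @param params monthly parameter table from [fit_stem_partition()].
#' @param truth a [sim_truth()] object.
#' @return data.frame: `month`, `parameter`, `truth`, `estimate`, `bias`,
#'   `rel_error`, `covered`.
#' @export
recovery_report <- function(params, truth) {
  tp <- truth$params
  months <- unique(params$month)
  if (!all(months %in% tp$month)) {
    stop("month mismatch: fitted months missing from the truth table")
  }
  out <- list()
  for (m in months) {
    trow <- tp[tp$month == m, ]
    for (p in c("R0", "b", "Pmax", "f", "e")) {
      prow <- params[params$month == m & params$parameter == p, ]
      if (nrow(prow) != 1) next
      tv <- trow[[p]]
      out[[length(out) + 1L]] <- data.frame(
        month = m, parameter = p, truth = tv, estimate = prow$estimate,
        bias = prow$estimate - tv,
        rel_error = (prow$estimate - tv) / tv,
        covered = prow$ci_lo <= tv & tv <= prow$ci_hi,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
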