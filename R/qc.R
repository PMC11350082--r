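# Quality control: technical checks, 3-SD outlier flagging, high-humidity
# removal, chamber alignment, and the low-sap-flow subset that conditions
# the respiration fit. All filters flag; rows are only dropped at assembly,
# so flag sets commute and the removal accounting is auditable.

#' Technical quality check on system diagnostics
#'
#' Flags records whose system flow rate, line pressure or closure-fit RMSE
#' fall outside the accepted instrument ranges. Checks are applied only for
#' diagnostics present in both `records` and `limits`; nothing is deleted.
#'
#' @param records flux record data.frame; may carry `flow`, `pressure`
#'   and/or `fit_rmse` columns.
#' @param limits named list of acceptance ranges, e.g.
#'   `list(flow = c(1.0, 1.2), pressure = c(95, 105), fit_rmse = c(0, 2))`.
#' @return `records` with `TECH_FAIL` added to `qc_flag` where any
#'   diagnostic is out of range.
#' @export
technical_qc <- function(records,
                         limits = list(flow = c(1.0, 1.2),
                                       pressure = c(95, 105),
                                       fit_rmse = c(0, 2))) {
  records$qc_flag <- norm_qc(records$qc_flag, nrow(records))
  bad <- rep(FALSE, nrow(records))
  for (nm in intersect(names(limits), names(records))) {
    rng <- limits[[nm]]
    x <- records[[nm]]
    bad <- bad | (!is.na(x) & (x < rng[1] | x > rng[2]))
  }
  records$qc_flag <- add_flag(records$qc_flag, which(bad), "TECH_FAIL")
  records
}

#' Flag flux outliers beyond three standard deviations
#'
#' Within each tree x chamber group, records whose flux deviates from the
#' group mean by more than `sd_mult` standard deviations are flagged
#' `OUTLIER_3SD`. Mean and SD are computed in a single pass over the
#' group's measured dataset (season-pooled by default), excluding only
#' technical failures — not records flagged by other environmental filters,
#' so the flag sets of the independent filters commute.
#'
#' @param records flux record data.frame with `fco2`, `tree_id`,
#'   `chamber_type`, `qc_flag`.
#' @param sd_mult multiplier on the standard deviation (default 3).
#' @param min_n minimum unflagged records per group; smaller groups are
#'   skipped with a warning.
#' @param monthly also split groups by calendar month.
#' @return `records` with outlier flags added.
#' @export
filter_outliers_3sd <- function(records, sd_mult = 3, min_n = 10,
                                monthly = FALSE) {
  records$qc_flag <- norm_qc(records$qc_flag, nrow(records))
  grp <- paste(records$tree_id, records$chamber_type)
  if (monthly) grp <- paste(grp, flux_month(records$timestamp))
  for (g in unique(grp)) {
    sel <- grp == g
    use <- sel & !has_flag(records$qc_flag, "TECH_FAIL") &
      is.finite(records$fco2)
    if (sum(use) < min_n) {
      warning(sprintf("group '%s' has fewer than %d clean records; skipped",
                      g, min_n))
      next
    }
    mu <- mean(records$fco2[use])
    sig <- stats::sd(records$fco2[use])
    out <- sel & is.finite(records$fco2) &
      abs(records$fco2 - mu) > sd_mult * sig
    records$qc_flag <- add_flag(records$qc_flag, which(out), "OUTLIER_3SD")
  }
  records
}

#' Flag records measured under high relative humidity
#'
#' Records whose closure-window mean RH exceeds the threshold are flagged
#' `RH_HIGH` (condensation risk in the sampling lines); records without RH
#' data are flagged `RH_MISSING` and treated as removed.
#'
#' @param records flux record data.frame.
#' @param drivers driver series with `timestamp` and `rh`.
#' @param threshold_pct RH threshold, percent (default 85).
#' @param window_s closure window over which RH is averaged when drivers are
#'   finer than the record grid, seconds.
#' @return `records` with humidity flags added.
#' @export
filter_high_rh <- function(records, drivers, threshold_pct = 85,
                           window_s = 100) {
  records$qc_flag <- norm_qc(records$qc_flag, nrow(records))
  idx <- match(records$timestamp, drivers$timestamp)
  rh <- drivers$rh[idx]
  if (anyNA(idx)) {
    # drivers on a finer grid: average RH over the closure window
    need <- which(is.na(idx))
    dts <- as.numeric(drivers$timestamp)
    for (i in need) {
      t0 <- as.numeric(records$timestamp[i])
      in_win <- dts >= t0 & dts <= t0 + window_s
      if (any(in_win)) rh[i] <- mean(drivers$rh[in_win])
    }
  }
  miss <- is.na(rh)
  records$qc_flag <- add_flag(records$qc_flag, which(miss), "RH_MISSING")
  records$qc_flag <- add_flag(records$qc_flag,
                              which(!miss & rh > threshold_pct), "RH_HIGH")
  records
}

#' Assemble the aligned dark/transparent analysis table
#'
#' Inner-joins the two chamber series on timestamp and tree, attaches the
#' drivers, and drops every row where either chamber record carries a QC
#' flag. The exclusion tally is attached as attribute `qc_counts` so that
#' removal accounting telescopes: rows in = flagged + rows out.
#'
#' @param dark,transparent flux record data.frames.
#' @param drivers driver series on the same (or finer) grid.
#' @return data.frame with columns `timestamp`, `tree_id`, `month`,
#'   `dfco2`, `tfco2`, `temp`, `ppfd`, `rh`, `j`.
#' @export
align_chambers <- function(dark, transparent, drivers) {
  m <- merge(dark[, c("timestamp", "tree_id", "fco2", "qc_flag")],
             transparent[, c("timestamp", "tree_id", "fco2", "qc_flag")],
             by = c("timestamp", "tree_id"),
             suffixes = c("_d", "_t"))
  if (nrow(m) == 0) stop("disjoint time ranges: no matching timestamps")
  di <- match(m$timestamp, drivers$timestamp)
  keep_cols <- intersect(c("temp", "ppfd", "rh", "j"), names(drivers))
  for (nm in keep_cols) m[[nm]] <- drivers[[nm]][di]
  flagged <- !is_clean(m$qc_flag_d) | !is_clean(m$qc_flag_t)
  out <- data.frame(timestamp = m$timestamp, tree_id = m$tree_id,
                    month = flux_month(m$timestamp),
                    dfco2 = m$fco2_d, tfco2 = m$fco2_t)
  for (nm in keep_cols) out[[nm]] <- m[[nm]]
  res <- out[!flagged, ]
  rownames(res) <- NULL
  attr(res, "qc_counts") <- list(
    n_dark = nrow(dark), n_transparent = nrow(transparent),
    n_matched = nrow(m),
    n_flagged = sum(flagged),
    n_flagged_dark = sum(!is_clean(m$qc_flag_d)),
    n_flagged_transparent = sum(!is_clean(m$qc_flag_t)),
    n_out = nrow(res))
  res
}

#' Select the low-sap-flow subset for the respiration fit
#'
#' Respiration is parameterized only under near-zero sap flow, when the
#' transport term is negligible and the dark-chamber flux is pure
#' respiration. The operative threshold is 5 (in the J unit convention of
#' the pipeline), equivalently expressible as a fraction (5%) of the
#' seasonal maximum hourly sap flux.
#'
#' @param table an aligned table from [align_chambers()] with a `j` column.
#' @param threshold fixed threshold on J (used when `mode = "fixed"`).
#' @param mode `"fixed"` or `"fraction_of_max"`.
#' @param fraction fraction of the seasonal maximum J defining the threshold
#'   in `"fraction_of_max"` mode.
#' @return the subset of rows with `j` below the threshold; attribute
#'   `n_retained` gives per-month retained counts, `threshold` the value
#'   applied. Months present in `table` but empty in the subset trigger a
#'   warning naming the month.
#' @export
select_low_sapflow <- function(table, threshold = 5,
                               mode = c("fixed", "fraction_of_max"),
                               fraction = 0.05) {
  mode <- match.arg(mode)
  if (is.null(table$j)) stop("`table` must have a `j` column")
  thr <- if (mode == "fixed") threshold else fraction * max(table$j, na.rm = TRUE)
  keep <- !is.na(table$j) & table$j < thr
  res <- table[keep, ]
  rownames(res) <- NULL
  months_in <- sort(unique(table$month))
  n_ret <- vapply(months_in, function(m) sum(res$month == m), integer(1))
  names(n_ret) <- month.abb[months_in]
  empty <- months_in[n_ret == 0]
  if (length(empty)) {
    warning(sprintf("no low-sap-flow rows in month(s): %s",
                    paste(month.abb[empty], collapse = ", ")))
  }
  attr(res, "n_retained") <- n_ret
  attr(res, "threshold") <- thr
  res
}

#' Per-filter QC accounting
#'
#' Counts how many records carry each QC flag, and how many are clean.
#'
#' @param records a flagged flux record data.frame.
#' @return named list of counts (`n_total`, `n_clean`, one entry per flag).
#' @export
qc_counts <- function(records) {
  flags <- unlist(strsplit(records$qc_flag[!is_clean(records$qc_flag)],
                           ";", fixed = TRUE))
  out <- list(n_total = nrow(records),
              n_clean = sum(is_clean(records$qc_flag)),
              n_flagged = sum(!is_clean(records$qc_flag)))
  for (f in sort(unique(flags))) out[[f]] <- sum(flags == f)
  out
}
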