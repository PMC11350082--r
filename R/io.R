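# CSV ingestion and artifact writing in a fixed column dialect with
# ISO-8601 UTC timestamps.

#' Read a timestamped CSV series
#'
#' Loads a CSV with an ISO-8601 `timestamp` column, validates the required
#' schema, parses timestamps as UTC, and canonicalizes row order (sorting
#' with a warning if the file is out of order). Unknown columns are
#' preserved.
#'
#' @param path file path.
#' @param required character vector of required column names (besides the
#'   timestamp column).
#' @param timestamp_col name of the timestamp column.
#' @return data.frame sorted by timestamp, `timestamp` as POSIXct UTC.
#' @export
read_timeseries <- function(path, required = character(),
                            timestamp_col = "timestamp") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(timestamp_col, required), names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- df[[timestamp_col]]
  ts <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01",
                   tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    need <- is.na(ts)
    if (!any(need)) break
    ts[need] <- as.POSIXct(strptime(raw[need], fmt, tz = "UTC"))
  }
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    stop(sprintf("unparseable timestamp(s) at row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  df[[timestamp_col]] <- ts
  if (is.unsorted(ts)) {
    warning("timestamps out of order; rows sorted")
    df <- df[order(ts), ]
    rownames(df) <- NULL
  }
  df
}

#' Write a timestamped series as CSV
#'
#' Timestamps are serialized as ISO-8601 UTC (`%Y-%m-%dT%H:%M:%SZ`);
#' `read_timeseries()` round-trips the values exactly.
#'
#' @param df data.frame with a POSIXct `timestamp` column.
#' @param path output file path.
#' @param timestamp_col name of the timestamp column.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(df, path, timestamp_col = "timestamp") {
  out <- df
  out[[timestamp_col]] <- format(df[[timestamp_col]], "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
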