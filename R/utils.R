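# Small shared helpers: QC flag strings, month extraction, clamping.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Calendar month of a timestamp
#'
#' @param ts a `POSIXct` vector.
#' @return integer month (1-12).
#' @export
flux_month <- function(ts) as.integer(format(ts, "%m"))

#' Hour of day of a timestamp
#'
#' @param ts a `POSIXct` vector.
#' @return integer hour (0-23).
#' @export
flux_hour <- function(ts) as.integer(format(ts, "%H"))

# QC flags are stored as ";"-separated tokens in a character column so that
# filters commute (flag-then-drop): no filter ever deletes or mutates a row.

#' Add a QC flag to selected records
#'
#' @param flags character vector of ";"-separated flag tokens ("" = clean).
#' @param idx logical or integer index of records to flag.
#' @param flag flag name to add.
#' @return updated flag vector.
#' @export
add_flag <- function(flags, idx, flag) {
  stopifnot(is.character(flags), is.character(flag), length(flag) == 1L)
  cur <- flags[idx]
  already <- has_flag(cur, flag)
  cur[!already] <- ifelse(nzchar(cur[!already]),
                          paste(cur[!already], flag, sep = ";"), flag)
  flags[idx] <- cur
  flags
}

#' Test whether records carry a given QC flag
#'
#' @inheritParams add_flag
#' @return logical vector.
#' @export
has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ";", fixed = TRUE),
         function(x) flag %in% x, logical(1))
}

#' Test whether records are unflagged
#'
#' @param flags character vector of flag tokens.
#' @return logical vector, `TRUE` where no flag is set.
#' @export
is_clean <- function(flags) !nzchar(flags)

# coerce a flag column to canonical form: character, "" for clean (columns
# written as all-empty CSV fields read back as logical NA)
norm_qc <- function(flags, n) {
  if (is.null(flags)) return(rep("", n))
  flags <- as.character(flags)
  flags[is.na(flags)] <- ""
  flags
}

stop_if_not_posix <- function(ts, what = "timestamp") {
  if (!inherits(ts, "POSIXct")) {
    stop(sprintf("`%s` must be POSIXct", what), call. = FALSE)
  }
}

check_aligned <- function(a, b, what = "series") {
  if (length(a) != length(b) || any(a != b)) {
    stop(sprintf("misaligned %s: timestamps differ", what), call. = FALSE)
  }
  invisible(TRUE)
}
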