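#' Column mapping and conventions for the trace CSV dialect
#'
#' Monitor trace exports differ in column naming, so all readers and writers
#' go through a dialect object. The shipped default describes the package's
#' documented dialect: one header row; a `time_s` column holding seconds
#' (numeric, nominal 2-second grid, gaps allowed); integer `spo2` percent and
#' `pr` beats-per-minute columns whose cells may instead carry the literal
#' invalid-entry tokens; a `pi` perfusion-index column; a `siq` column with
#' values `ok`/`low`; and an `events` column of semicolon-delimited event
#' tokens. Two comment lines (`# neonate_id: ...`, `# device_id: ...`)
#' precede the header. Timestamps can alternatively be ISO-8601 strings
#' (`time = "iso8601"`); they are normalized to seconds from trace start on
#' read.
#'
#' @param col_time,col_spo2,col_pr,col_pi,col_siq,col_events Column names in
#'   the file.
#' @param time Either `"seconds"` or `"iso8601"`.
#' @param events_sep Separator between event tokens within the events column.
#' @param invalid_spo2,invalid_pr Literal tokens marking invalid readings.
#' @return A list of class `trace_dialect`.
#' @export
trace_dialect <- function(col_time = "time_s", col_spo2 = "spo2",
                          col_pr = "pr", col_pi = "pi", col_siq = "siq",
                          col_events = "events", time = c("seconds", "iso8601"),
                          events_sep = ";",
                          invalid_spo2 = invalid_spo2_token(),
                          invalid_pr = invalid_pr_token()) {
  time <- match.arg(time)
  structure(list(
    col_time = col_time, col_spo2 = col_spo2, col_pr = col_pr,
    col_pi = col_pi, col_siq = col_siq, col_events = col_events,
    time = time, events_sep = events_sep,
    invalid_spo2 = invalid_spo2, invalid_pr = invalid_pr
  ), class = "trace_dialect")
}

#' Construct a pulse-oximeter trace
#'
#' A trace is one neonate's 0.5 Hz time series: per 2-second data cell, the
#' oxygen saturation (`spo2`, integer percent or `NA`), pulse rate (`pr`,
#' integer bpm or `NA`), perfusion index (`pi`), signal quality flag (`siq`,
#' `"ok"`/`"low"`) and a delimited string of event tokens. Timestamps `t` are
#' seconds from trace start on a strictly increasing grid whose spacing is a
#' positive multiple of the 2-second sample interval (gaps allowed, never
#' imputed).
#'
#' @param samples Data frame with columns `t`, `spo2`, `pr`, `pi`, `siq`,
#'   `events` (and optionally `excluded` on filtered traces).
#' @param neonate_id,device_id Opaque identifiers.
#' @param validate Check invariants (default `TRUE`).
#' @return An object of class `ox_trace`.
#' @export
ox_trace <- function(samples, neonate_id = "unknown", device_id = "unknown",
                     validate = TRUE) {
  needed <- c("t", "spo2", "pr", "pi", "siq", "events")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols) > 0L) {
    stop("samples is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  tr <- structure(list(
    neonate_id = as.character(neonate_id),
    device_id = as.character(device_id),
    sample_interval_s = 2,
    samples = samples
  ), class = "ox_trace")
  if (validate) validate_trace(tr)
  tr
}

#' Validate trace invariants
#'
#' Errors (citing the first offending row) if timestamps are not strictly
#' increasing on the 2-second grid, if values fall outside their physical
#' ranges, or if an invalid-entry token is present while the corresponding
#' value is not null.
#'
#' @param trace An `ox_trace`.
#' @param dialect Dialect supplying the invalid tokens.
#' @return The trace, invisibly.
#' @export
validate_trace <- function(trace, dialect = trace_dialect()) {
  s <- trace$samples
  if (nrow(s) == 0L) stop("trace has no samples")
  dt <- diff(s$t)
  bad <- which(dt <= 0)
  if (length(bad) > 0L) {
    stop(sprintf("timestamps not strictly increasing at row %d", bad[1] + 1L))
  }
  off <- which(abs(dt / trace$sample_interval_s -
                     round(dt / trace$sample_interval_s)) > 1e-9)
  if (length(off) > 0L) {
    stop(sprintf("timestamp spacing not a multiple of %ds at row %d",
                 trace$sample_interval_s, off[1] + 1L))
  }
  chk_range <- function(x, lo, hi, what) {
    bad <- which(!is.na(x) & (x < lo | x > hi))
    if (length(bad) > 0L) {
      stop(sprintf("%s out of range [%g, %g] at row %d", what, lo, hi, bad[1]))
    }
  }
  chk_range(s$spo2, 0, 100, "spo2")
  chk_range(s$pr, 0, Inf, "pr")
  chk_range(s$pi, 0, Inf, "pi")
  if (!all(s$siq %in% c("ok", "low"))) stop("siq must be 'ok' or 'low'")
  inv_spo2 <- has_token(s$events, dialect$invalid_spo2, dialect$events_sep)
  if (any(inv_spo2 & !is.na(s$spo2))) {
    stop(sprintf("spo2 not null despite invalid-SpO2 token at row %d",
                 which(inv_spo2 & !is.na(s$spo2))[1]))
  }
  inv_pr <- has_token(s$events, dialect$invalid_pr, dialect$events_sep)
  if (any(inv_pr & !is.na(s$pr))) {
    stop(sprintf("pr not null despite invalid-PR token at row %d",
                 which(inv_pr & !is.na(s$pr))[1]))
  }
  invisible(trace)
}

#' @export
print.ox_trace <- function(x, ...) {
  s <- x$samples
  cat(sprintf("<ox_trace> neonate %s on device %s\n", x$neonate_id, x$device_id))
  cat(sprintf("  %d cells (%.2f h), %.1f%% SpO2 null, %.1f%% PR null\n",
              nrow(s), nrow(s) * x$sample_interval_s / 3600,
              100 * mean(is.na(s$spo2)), 100 * mean(is.na(s$pr))))
  n_alarm <- sum(nzchar(s$events) & !is.na(s$events))
  cat(sprintf("  %d cells carry event tokens%s\n", n_alarm,
              if ("excluded" %in% names(s))
                sprintf("; %d cells excluded", sum(s$excluded)) else ""))
  invisible(x)
}

#' Read a pulse-oximeter trace CSV
#'
#' Reads one per-neonate trace file in the documented dialect (see
#' [trace_dialect()]). Cells of the SpO2/PR columns holding the literal
#' invalid-entry tokens become null values, with the token retained in the
#' cell's event labels so no information is lost. Timestamps are normalized
#' to seconds from trace start.
#'
#' @param path File path.
#' @param dialect Column mapping, see [trace_dialect()].
#' @param neonate_id,device_id Identifiers; default taken from the file's
#'   comment header (or `"unknown"`).
#' @return An `ox_trace`.
#' @export
read_trace_csv <- function(path, dialect = trace_dialect(),
                           neonate_id = NULL, device_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 10L)
  meta <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(m) == 0L) return(NULL)
    trimws(sub(paste0("^#\\s*", key, ":"), "", m[1]))
  }
  neonate_id <- neonate_id %||% get_meta("neonate_id") %||% "unknown"
  device_id <- device_id %||% get_meta("device_id") %||% "unknown"

  raw <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         colClasses = "character", check.names = FALSE)
  for (col in c("col_time", "col_spo2", "col_pr", "col_pi", "col_siq",
                "col_events")) {
    if (!(dialect[[col]] %in% names(raw))) {
      stop(sprintf("required column '%s' (%s) not found in %s",
                   dialect[[col]], col, path))
    }
  }
  n <- nrow(raw)
  if (n == 0L) stop("no data rows in ", path)

  if (dialect$time == "iso8601") {
    ts <- as.POSIXct(raw[[dialect$col_time]], tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(ts)) {
      stop(sprintf("unparsable timestamp at row %d in %s", which(is.na(ts))[1],
                   path))
    }
    t <- as.numeric(ts) - as.numeric(ts[1])
  } else {
    t <- suppressWarnings(as.numeric(raw[[dialect$col_time]]))
    if (anyNA(t)) {
      stop(sprintf("unparsable timestamp at row %d in %s", which(is.na(t))[1],
                   path))
    }
  }

  events <- raw[[dialect$col_events]]
  events[is.na(events)] <- ""

  parse_vital <- function(x, invalid_token, what) {
    is_invalid <- trimws(x) == invalid_token
    is_blank <- is.na(x) | !nzchar(trimws(x))
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is_invalid & !is_blank & is.na(v))
    if (length(bad) > 0L) {
      stop(sprintf("unparsable %s value '%s' at row %d in %s", what,
                   x[bad[1]], bad[1], path))
    }
    v[is_invalid] <- NA_real_
    list(value = v, invalid = is_invalid)
  }
  spo2 <- parse_vital(raw[[dialect$col_spo2]], dialect$invalid_spo2, "spo2")
  pr <- parse_vital(raw[[dialect$col_pr]], dialect$invalid_pr, "pr")
  pi_col <- suppressWarnings(as.numeric(raw[[dialect$col_pi]]))

  # retain invalid-entry tokens as labels (idempotent if already present)
  add_token <- function(events, which, token) {
    need <- which & !has_token(events, token, dialect$events_sep)
    events[need] <- ifelse(nzchar(events[need]),
                           paste(events[need], token, sep = dialect$events_sep),
                           token)
    events
  }
  events <- add_token(events, spo2$invalid, dialect$invalid_spo2)
  events <- add_token(events, pr$invalid, dialect$invalid_pr)

  siq <- tolower(trimws(raw[[dialect$col_siq]]))
  siq[!nzchar(siq)] <- "ok"

  samples <- data.frame(
    t = t, spo2 = spo2$value, pr = pr$value, pi = pi_col,
    siq = siq, events = events, stringsAsFactors = FALSE
  )
  ox_trace(samples, neonate_id, device_id)
}

#' Write a pulse-oximeter trace CSV
#'
#' Emits the documented dialect. Null SpO2/PR values are rendered as the
#' invalid-entry tokens whenever the corresponding invalid label is present,
#' so that `read_trace_csv(write_trace_csv(trace))` is the identity; plain
#' missing values are written as empty cells. Output is bit-deterministic for
#' a fixed trace.
#'
#' @param trace An `ox_trace`.
#' @param path Output file path.
#' @param dialect Column mapping, see [trace_dialect()].
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, dialect = trace_dialect()) {
  validate_trace(trace, dialect)
  s <- trace$samples
  fmt_vital <- function(v, invalid_mask, token) {
    out <- ifelse(is.na(v), "", format(v, trim = TRUE, scientific = FALSE))
    out[invalid_mask] <- token
    out
  }
  inv_spo2 <- has_token(s$events, dialect$invalid_spo2, dialect$events_sep)
  inv_pr <- has_token(s$events, dialect$invalid_pr, dialect$events_sep)
  out <- data.frame(
    a = s$t,
    b = fmt_vital(s$spo2, inv_spo2, dialect$invalid_spo2),
    c = fmt_vital(s$pr, inv_pr, dialect$invalid_pr),
    d = ifelse(is.na(s$pi), "", format(s$pi, trim = TRUE, scientific = FALSE)),
    e = s$siq,
    f = s$events,
    stringsAsFactors = FALSE
  )
  names(out) <- c(dialect$col_time, dialect$col_spo2, dialect$col_pr,
                  dialect$col_pi, dialect$col_siq, dialect$col_events)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("# neonate_id: ", trace$neonate_id),
               paste0("# device_id: ", trace$device_id)), con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}
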