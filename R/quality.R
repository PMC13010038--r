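#' Apply data-integrity exclusions to a trace
#'
#' Implements the study's quality rules on one trace:
#'
#' * cells carrying the invalid-SpO2 or invalid-PR tokens keep their null
#'   value (counted in the report);
#' * cells inside system-event segments (sensor off, low perfusion, cable
#'   disconnect) or with invalid readings are marked `excluded`, and any
#'   clinical alarm labels on them are removed from the clinical alarm
#'   stream;
#' * clinical alarm labels on low-SIQ cells are removed from the alarm stream
#'   (the SpO2/PR samples themselves are retained for re-simulation when
#'   valid).
#'
#' Exclusions are a union over rules, so the excluded duration is the total
#' time of cells flagged by any rule. Filtering is idempotent. Removed alarm
#' entries never reach event segmentation.
#'
#' @param trace An `ox_trace`.
#' @param mapping Label table, see [default_label_map()].
#' @param dialect Dialect supplying token conventions.
#' @return A list with elements `trace` (the filtered trace, gaining an
#'   `excluded` logical column) and `report` (a `quality_report`).
#' @export
apply_quality_rules <- function(trace, mapping = default_label_map(),
                                dialect = trace_dialect()) {
  s <- trace$samples
  sep <- dialect$events_sep
  n <- nrow(s)

  inv_spo2 <- has_token(s$events, dialect$invalid_spo2, sep)
  inv_pr <- has_token(s$events, dialect$invalid_pr, sep)
  system_tokens <- setdiff(exclusion_tokens(),
                           c(dialect$invalid_spo2, dialect$invalid_pr))
  sys_cell <- has_token(s$events, system_tokens, sep)
  excluded <- inv_spo2 | inv_pr | sys_cell
  low_siq <- s$siq == "low"

  clinical_tokens <- mapping$raw[mapping$category %in% clinical_categories()]
  has_clin <- has_token(s$events, clinical_tokens, sep)

  count_clinical_tokens <- function(ev) {
    if (length(ev) == 0L) return(0L)
    uniq <- unique(ev)
    cnt <- vapply(uniq, function(x) {
      if (is.na(x) || !nzchar(x)) return(0L)
      sum(trimws(strsplit(x, sep, fixed = TRUE)[[1]]) %in% clinical_tokens)
    }, integer(1), USE.NAMES = FALSE)
    sum(cnt[match(ev, uniq)])
  }
  n_siq_removed <- count_clinical_tokens(s$events[low_siq & !excluded])
  n_alarms_in_excluded <- count_clinical_tokens(s$events[excluded])

  strip_mask <- (low_siq | excluded) & has_clin
  s$events <- strip_tokens(s$events, strip_mask, clinical_tokens, sep)
  s$excluded <- excluded

  sys_breakdown <- integer(0)
  if (any(sys_cell)) {
    tok <- unlist(lapply(strsplit(s$events[sys_cell], sep, fixed = TRUE),
                         trimws))
    tok <- tok[tok %in% system_tokens]
    sys_breakdown <- table(tok)
  }

  total_h <- n * trace$sample_interval_s / 3600
  excl_h <- sum(excluded) * trace$sample_interval_s / 3600
  report <- structure(list(
    neonate_id = trace$neonate_id,
    total_duration_h = total_h,
    excluded_duration_h = excl_h,
    excluded_fraction = if (n > 0) excl_h / total_h else 0,
    n_invalid_spo2 = sum(inv_spo2),
    n_invalid_pr = sum(inv_pr),
    n_low_siq_alarm_entries_removed = n_siq_removed,
    n_alarm_entries_in_excluded = n_alarms_in_excluded,
    system_event_breakdown = as.list(sys_breakdown),
    spo2_null_fraction_in_excluded =
      if (any(excluded)) mean(is.na(s$spo2[excluded])) else NA_real_,
    pr_null_fraction_in_excluded =
      if (any(excluded)) mean(is.na(s$pr[excluded])) else NA_real_,
    density_denominator = "quality-passing hours"
  ), class = "quality_report")

  filtered <- trace
  filtered$samples <- s
  list(trace = filtered, report = report)
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report> neonate %s\n", x$neonate_id))
  cat(sprintf("  monitored: %.2f h, excluded: %.2f h (%.2f%%)\n",
              x$total_duration_h, x$excluded_duration_h,
              100 * x$excluded_fraction))
  cat(sprintf("  invalid SpO2 cells: %d; invalid PR cells: %d\n",
              x$n_invalid_spo2, x$n_invalid_pr))
  cat(sprintf("  alarm entries removed for low SIQ: %d; in excluded cells: %d\n",
              x$n_low_siq_alarm_entries_removed, x$n_alarm_entries_in_excluded))
  if (length(x$system_event_breakdown) > 0) {
    cat("  system events (cells): ",
        paste(names(x$system_event_breakdown),
              unlist(x$system_event_breakdown), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.na(x$spo2_null_fraction_in_excluded)) {
    cat(sprintf("  null fraction in excluded cells: SpO2 %.1f%%, PR %.1f%%\n",
                100 * x$spo2_null_fraction_in_excluded,
                100 * x$pr_null_fraction_in_excluded))
  }
  cat("  density denominator downstream: ", x$density_denominator, "\n",
      sep = "")
  invisible(x)
}

#' Serialize a quality report
#'
#' Writes both a flat key-value text rendering and a machine-readable JSON
#' file next to it (same stem, `.json` extension).
#'
#' @param report A `quality_report`.
#' @param path Output path for the text report.
#' @return `path`, invisibly.
#' @export
write_quality_report <- function(report, path) {
  txt <- utils::capture.output(print(report))
  writeLines(txt, path)
  jsonlite::write_json(unclass(report), sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Monitored hours of a trace
#'
#' Hours covered by data cells: 2 seconds per cell. With
#' `include_excluded = FALSE` (the default) only quality-passing cells count;
#' a trace that has not been through [apply_quality_rules()] has no
#' exclusions yet, so all cells count.
#'
#' @param trace An `ox_trace`.
#' @param include_excluded Count excluded cells too?
#' @return Hours (numeric scalar).
#' @export
monitored_hours <- function(trace, include_excluded = FALSE) {
  s <- trace$samples
  n <- nrow(s)
  if (n == 0L) return(0)
  if (!include_excluded && "excluded" %in% names(s)) {
    n <- sum(!s$excluded)
  }
  n * trace$sample_interval_s / 3600
}

# Validity masks used by pooled statistics and the simulator: a sample is
# usable when its value is present and its cell passed the quality rules.
valid_mask <- function(trace, parameter = c("spo2", "pr")) {
  parameter <- match.arg(parameter)
  s <- trace$samples
  ok <- !is.na(s[[parameter]])
  if ("excluded" %in% names(s)) ok <- ok & !s$excluded
  ok
}
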