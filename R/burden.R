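#' Alarm density
#'
#' Number of alarm events per monitored hour. The denominator should be
#' quality-passing hours (see [monitored_hours()]).
#'
#' @param events Event table (or anything with one row per event).
#' @param hours Monitored hours, must be positive.
#' @return Alarms per hour.
#' @export
alarm_density <- function(events, hours) {
  if (!is.numeric(hours) || length(hours) != 1L || is.na(hours) || hours <= 0) {
    stop("undefined density: monitored hours must be a positive number")
  }
  n <- if (is.data.frame(events)) nrow(events) else length(events)
  n / hours
}

#' Duration distribution over buckets
#'
#' Percentage of events falling into duration buckets delimited by `edges`.
#' Buckets are left-open and right-closed, so with an edge at 30 the first
#' bucket is "30 seconds or less" and an event of exactly 30 s falls inside
#' it.
#'
#' @param events Event table with a `duration_s` column (or a numeric vector
#'   of durations in seconds).
#' @param edges Strictly increasing bucket edges in seconds.
#' @return Named numeric vector of percentages (sums to 100 up to rounding).
#' @export
duration_bucket_percentages <- function(events, edges = c(30, 60, 120, 300, 600)) {
  d <- if (is.data.frame(events)) events$duration_s else events
  d <- d[!is.na(d)]
  if (length(d) == 0L) stop("no events: duration distribution undefined")
  if (is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be strictly increasing")
  }
  breaks <- c(-Inf, edges, Inf)
  cuts <- cut(d, breaks = breaks, right = TRUE)
  pct <- 100 * as.vector(table(cuts)) / length(d)
  lab <- c(sprintf("<=%gs", edges[1]),
           if (length(edges) > 1)
             sprintf("(%gs,%gs]", edges[-length(edges)], edges[-1]),
           sprintf(">%gs", edges[length(edges)]))
  stats::setNames(pct, lab)
}

#' Fraction of valid samples outside a threshold pair
#'
#' Computes the fraction of valid samples strictly below `low` and strictly
#' above `high` (a value equal to a threshold is in range, matching the
#' monitor's within-range limits). A `NULL` threshold means that side is
#' disabled and its fraction is 0. Denominators are valid samples only
#' (non-null, quality-passing).
#'
#' @param x An `ox_trace`, a list of traces, or a numeric vector of pooled
#'   valid samples.
#' @param low,high Thresholds (either may be `NULL` = disabled).
#' @param parameter `"spo2"` or `"pr"` (ignored when `x` is numeric).
#' @return A list with elements `below` and `above` (proportions in
#'   \[0, 1\]).
#' @export
out_of_range_fraction <- function(x, low, high, parameter = c("spo2", "pr")) {
  parameter <- match.arg(parameter)
  v <- pooled_values(x, parameter)
  if (length(v) == 0L) stop("no valid samples for parameter ", parameter)
  list(
    below = if (is.null(low)) 0 else mean(v < low),
    above = if (is.null(high)) 0 else mean(v > high)
  )
}

# Pool valid samples from a trace, list of traces, or numeric vector.
pooled_values <- function(x, parameter) {
  if (is.numeric(x)) return(x[!is.na(x)])
  if (inherits(x, "ox_trace")) x <- list(x)
  unlist(lapply(x, function(tr) {
    tr$samples[[parameter]][valid_mask(tr, parameter)]
  }), use.names = FALSE)
}

#' Per-neonate burden statistics
#'
#' Summarizes an event table into one row per neonate: total alarm count,
#' alarms per hour, median and IQR (Q3 - Q1) of event durations, counts per
#' category, and audible/visual densities. An `audio_visual` event
#' contributes to both the audible and the visual stream, matching how
#' visual and audible densities overlap in the totals.
#'
#' @param events Event table pooled over neonates (see [segment_events()]).
#' @param hours Named numeric vector of quality-passing monitored hours per
#'   neonate id.
#' @return A data frame with one row per neonate.
#' @export
per_neonate_burden <- function(events, hours) {
  ids <- names(hours)
  if (is.null(ids)) stop("`hours` must be a named vector (neonate ids)")
  rows <- lapply(ids, function(id) {
    ev <- events[events$neonate_id == id, , drop = FALSE]
    h <- hours[[id]]
    aud <- ev$modality %in% c("audible", "audio_visual")
    vis <- ev$modality %in% c("visual", "audio_visual")
    cat_counts <- vapply(c(clinical_categories(), "system"),
                         function(cc) sum(ev$category == cc), integer(1))
    data.frame(
      neonate_id = id,
      hours = h,
      n_alarms = nrow(ev),
      alarms_per_hour = if (h > 0) nrow(ev) / h else NA_real_,
      audible_per_hour = if (h > 0) sum(aud) / h else NA_real_,
      visual_per_hour = if (h > 0) sum(vis) / h else NA_real_,
      median_duration_s = median_na(ev$duration_s),
      iqr_duration_s = iqr_width(ev$duration_s),
      n_spo2_low = cat_counts[["spo2_low"]],
      n_spo2_high = cat_counts[["spo2_high"]],
      n_pr_low = cat_counts[["pr_low"]],
      n_pr_high = cat_counts[["pr_high"]],
      n_system = cat_counts[["system"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort burden summary
#'
#' Aggregates per-neonate burden statistics into cohort-level summaries:
#' median and IQR (Q3 - Q1, quartiles by linear interpolation) of the
#' per-neonate values — never of pooled cells — plus duration-bucket
#' percentages over all events, and the maximum alarm count in any single
#' hour and any single day. Hour/day windows are clock-aligned from each
#' neonate's first sample.
#'
#' @param per_neonate Data frame from [per_neonate_burden()].
#' @param events Optional pooled event table for duration buckets and maxima.
#' @param edges Duration bucket edges in seconds.
#' @return A list of class `burden_summary` with elements `per_neonate` and
#'   `cohort`.
#' @export
cohort_summary <- function(per_neonate, events = NULL,
                           edges = c(30, 60, 120, 300, 600)) {
  stopifnot(nrow(per_neonate) >= 1L)
  med_iqr <- function(x) c(median = median_na(x), iqr = iqr_width(x))
  cohort <- list(
    n_neonates = nrow(per_neonate),
    total_alarms = sum(per_neonate$n_alarms),
    alarms_per_neonate = med_iqr(per_neonate$n_alarms),
    density_per_hour = med_iqr(per_neonate$alarms_per_hour),
    audible_density_per_hour = med_iqr(per_neonate$audible_per_hour),
    visual_density_per_hour = med_iqr(per_neonate$visual_per_hour),
    median_duration_s = med_iqr(per_neonate$median_duration_s)
  )
  if (!is.null(events) && nrow(events) > 0L) {
    cohort$duration_buckets_pct <- duration_bucket_percentages(events, edges)
    cohort$pooled_median_duration_s <- median_na(events$duration_s)
    cohort$pooled_iqr_duration_s <- iqr_width(events$duration_s)
    win_max <- function(width_s) {
      counts <- unlist(lapply(split(events$start_t, events$neonate_id),
                              function(t) {
                                if (length(t) == 0L) return(0L)
                                tabulate(floor((t - min(t)) / width_s) + 1L)
                              }), use.names = FALSE)
      if (length(counts) == 0L) 0L else max(counts)
    }
    cohort$max_hourly_count <- win_max(3600)
    cohort$max_daily_count <- win_max(86400)
  }
  structure(list(per_neonate = per_neonate, cohort = cohort),
            class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  co <- x$cohort
  fmt <- function(v) sprintf("%.3g (IQR, %.3g)", v[["median"]], v[["iqr"]])
  cat(sprintf("<burden_summary> %d neonates, %d alarm events\n",
              co$n_neonates, co$total_alarms))
  cat("  alarms per neonate:       ", fmt(co$alarms_per_neonate), "\n")
  cat("  density per hour:         ", fmt(co$density_per_hour), "\n")
  cat("  audible density per hour: ", fmt(co$audible_density_per_hour), "\n")
  cat("  visual density per hour:  ", fmt(co$visual_density_per_hour), "\n")
  if (!is.null(co$duration_buckets_pct)) {
    cat(sprintf("  pooled median duration:    %g s (IQR, %g s)\n",
                co$pooled_median_duration_s, co$pooled_iqr_duration_s))
    cat("  duration buckets: ",
        paste(names(co$duration_buckets_pct),
              sprintf("%.1f%%", co$duration_buckets_pct),
              sep = " ", collapse = ", "), "\n")
    cat(sprintf("  max hourly count: %d; max daily count: %d\n",
                co$max_hourly_count, co$max_daily_count))
  }
  invisible(x)
}

#' Serialize a burden summary
#'
#' Writes the per-neonate table as CSV, a machine-readable JSON summary and
#' a plain-text report.
#'
#' @param x A `burden_summary`.
#' @param stem Output path stem; writes `<stem>_per_neonate.csv`,
#'   `<stem>.json`, `<stem>.txt`.
#' @return Character vector of written paths, invisibly.
#' @export
write_burden_summary <- function(x, stem) {
  paths <- c(
    per_neonate = paste0(stem, "_per_neonate.csv"),
    json = paste0(stem, ".json"),
    txt = paste0(stem, ".txt")
  )
  utils::write.csv(x$per_neonate, paths[["per_neonate"]], row.names = FALSE)
  co <- x$cohort
  co$duration_buckets_pct <- as.list(co$duration_buckets_pct)
  jsonlite::write_json(co, paths[["json"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  writeLines(utils::capture.output(print(x)), paths[["txt"]])
  invisible(paths)
}
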