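#' Monitor alarm settings
#'
#' The configuration driving alarm generation, defaulting to the device
#' settings used at study setup: trailing averaging over 8 s, an alarm delay
#' of 15 s, a rapid-desaturation margin of 10 percentage points below the
#' lower SpO2 threshold, within-range limits of 85-96% SpO2 and 90-200 bpm
#' PR. An upper threshold of `NULL` disables that alarm. `sensitivity` and
#' `fast_sat` are carried as metadata with no computational effect (Fast sat
#' is OFF in the study configuration).
#'
#' @param spo2_low,spo2_high SpO2 thresholds in percent (`spo2_high = NULL`
#'   disables the high alarm).
#' @param pr_low,pr_high PR thresholds in bpm (`pr_high = NULL` disables).
#' @param delay_s Alarm delay in seconds: a violation must persist this long
#'   (in whole 2 s cells) before the alarm asserts.
#' @param averaging_s Trailing averaging window in seconds (positive
#'   multiple of 2).
#' @param rapid_desat_pct Rapid-desaturation margin in percentage points; an
#'   averaged SpO2 at or below `spo2_low - rapid_desat_pct` asserts the low
#'   alarm immediately, bypassing the delay.
#' @param sensitivity,fast_sat Metadata labels.
#' @return A list of class `alarm_settings`.
#' @export
alarm_settings <- function(spo2_low = 85, spo2_high = 96,
                           pr_low = 90, pr_high = 200,
                           delay_s = 15, averaging_s = 8,
                           rapid_desat_pct = 10,
                           sensitivity = "normal", fast_sat = "off") {
  if (!is.null(spo2_high) && spo2_low >= spo2_high) {
    stop("spo2_low must be below spo2_high")
  }
  if (!is.null(pr_high) && pr_low >= pr_high) {
    stop("pr_low must be below pr_high")
  }
  stopifnot(delay_s >= 0, averaging_s > 0, averaging_s %% 2 == 0,
            rapid_desat_pct >= 0)
  structure(list(
    spo2_low = spo2_low, spo2_high = spo2_high,
    pr_low = pr_low, pr_high = pr_high,
    delay_s = delay_s, averaging_s = averaging_s,
    rapid_desat_pct = rapid_desat_pct,
    sensitivity = sensitivity, fast_sat = fast_sat
  ), class = "alarm_settings")
}

#' Trailing moving average with nulls
#'
#' Trailing boxcar over `window_s / interval_s` samples. Partial windows at
#' the series start average the available samples; null samples are excluded
#' from the window, and a window containing only nulls yields null. With
#' `window_s = interval_s` this is the identity.
#'
#' @param x Numeric vector (may contain `NA`).
#' @param window_s Window length in seconds (positive multiple of the sample
#'   interval).
#' @param interval_s Sample interval in seconds (default 2).
#' @return Numeric vector of the same length.
#' @export
moving_average <- function(x, window_s, interval_s = 2) {
  k <- window_s / interval_s
  if (k < 1 || abs(k - round(k)) > 1e-9) {
    stop("window_s must be a positive multiple of the sample interval")
  }
  k <- as.integer(round(k))
  if (k == 1L) return(x)
  n <- length(x)
  if (n == 0L) return(x)
  vals <- ifelse(is.na(x), 0, x)
  cs <- cumsum(vals)
  cn <- cumsum(!is.na(x))
  lag_cs <- c(rep(0, k), cs[seq_len(n - k)])[seq_len(n)]
  lag_cn <- c(rep(0L, k), cn[seq_len(n - k)])[seq_len(n)]
  sums <- cs - lag_cs
  cnts <- cn - lag_cn
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  out
}

# Per-cell alarm activity for one parameter/direction. Returns indices of
# cells where the alarm is asserted.
#
# Semantics: the violation indicator is computed on the averaged series with
# strict inequalities; the alarm asserts at the first cell where the
# violation has been continuously true (contiguous 2 s cells, a timestamp
# gap breaks continuity) for at least delay_s, and de-asserts when the
# violation clears. For the low-SpO2 alarm, an averaged value at or below
# spo2_low - rapid_desat_pct asserts immediately for the remainder of the
# violation run.
active_cells_one <- function(t, avg, threshold, direction, delay_s,
                             interval_s = 2, deep_threshold = NULL) {
  if (is.null(threshold)) return(integer(0))
  viol <- if (direction == "low") !is.na(avg) & avg < threshold else
    !is.na(avg) & avg > threshold
  idx <- which(viol)
  if (length(idx) == 0L) return(integer(0))
  vt <- t[idx]
  new_run <- c(TRUE, diff(vt) != interval_s | diff(idx) != 1L)
  rid <- cumsum(new_run)
  pos <- seq_along(idx) - cummax(ifelse(new_run, seq_along(idx) - 1L, 0L))
  d <- max(1L, as.integer(ceiling(delay_s / interval_s)))
  assert_at <- rep(d, length(idx))
  if (!is.null(deep_threshold)) {
    deep <- avg[idx] <= deep_threshold
    if (any(deep)) {
      first_deep <- group_min(ifelse(deep, pos, Inf), rid)
      assert_at <- pmin(assert_at, first_deep[rid])
    }
  }
  idx[pos >= assert_at]
}

#' Per-cell simulated alarm activity
#'
#' Re-derives the monitor's per-cell alarm state from raw SpO2/PR values
#' under the given settings: trailing averaging, strict threshold check,
#' alarm delay in whole 2 s cells, and the rapid-desaturation override for
#' the low-SpO2 alarm. Samples that are null or on excluded cells are
#' unavailable to the simulator; a timestamp gap breaks violation
#' continuity.
#'
#' @param trace An `ox_trace` (normally quality-filtered).
#' @param settings An [alarm_settings()].
#' @return A named list of integer cell-index vectors (`spo2_low`,
#'   `spo2_high`, `pr_low`, `pr_high`).
#' @export
alarm_active_cells <- function(trace, settings = alarm_settings()) {
  s <- trace$samples
  iv <- trace$sample_interval_s
  spo2 <- s$spo2
  pr <- s$pr
  spo2[!valid_mask(trace, "spo2")] <- NA_real_
  pr[!valid_mask(trace, "pr")] <- NA_real_
  avg_spo2 <- moving_average(spo2, settings$averaging_s, iv)
  avg_pr <- moving_average(pr, settings$averaging_s, iv)
  list(
    spo2_low = active_cells_one(
      s$t, avg_spo2, settings$spo2_low, "low", settings$delay_s, iv,
      deep_threshold = settings$spo2_low - settings$rapid_desat_pct),
    spo2_high = active_cells_one(
      s$t, avg_spo2, settings$spo2_high, "high", settings$delay_s, iv),
    pr_low = active_cells_one(
      s$t, avg_pr, settings$pr_low, "low", settings$delay_s, iv),
    pr_high = active_cells_one(
      s$t, avg_pr, settings$pr_high, "high", settings$delay_s, iv)
  )
}

#' Simulate the monitor's alarm stream
#'
#' Runs the alarm state machine of [alarm_active_cells()] and segments the
#' asserted cells into alarm events under the gap rule, exactly as recorded
#' annotations are segmented. Simulated events carry modality
#' `audio_visual` (the device annunciates both; silencing is an operator
#' action, not derivable from the values).
#'
#' @param trace An `ox_trace` (normally quality-filtered).
#' @param settings An [alarm_settings()].
#' @param config A [segmentation_config()].
#' @return An event table like [segment_events()]'s.
#' @export
simulate_alarm_stream <- function(trace, settings = alarm_settings(),
                                  config = segmentation_config()) {
  act <- alarm_active_cells(trace, settings)
  iv <- config$sample_interval_s
  out <- lapply(names(act), function(cat) {
    idx <- act[[cat]]
    if (length(idx) == 0L) return(NULL)
    ev <- events_from_cells(trace$samples$t[idx], config$gap_s, iv)
    ev$category <- cat
    ev
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_event_table())
  out$neonate_id <- trace$neonate_id
  out <- out[order(out$start_t, out$category),
             c("neonate_id", "category", "modality", "start_t", "end_t",
               "active_cell_count", "duration_s", "merged_across_gap")]
  rownames(out) <- NULL
  out
}

#' Count alarm activations
#'
#' Number of alarm annunciations: maximal contiguous runs of asserted cells
#' (equivalently, the event count under a gap of 0). Unlike gap-merged event
#' counts — where deleting cells can split a merged chain — the activation
#' count is provably non-increasing in the alarm delay, which makes it the
#' right quantity for delay what-if comparisons.
#'
#' @param trace An `ox_trace`.
#' @param settings An [alarm_settings()].
#' @return Named integer vector over the four clinical categories.
#' @export
alarm_activation_counts <- function(trace, settings = alarm_settings()) {
  act <- alarm_active_cells(trace, settings)
  iv <- trace$sample_interval_s
  vapply(act, function(idx) {
    if (length(idx) == 0L) return(0L)
    tt <- trace$samples$t[idx]
    1L + sum(diff(tt) > iv)
  }, integer(1))
}

#' Build a grid of alarm settings
#'
#' Expands the cross-product of the supplied values into a list of
#' [alarm_settings()]. Use `list(NULL)` entries (or `NA`) for disabled upper
#' thresholds.
#'
#' @param spo2_low,spo2_high,pr_low,pr_high,delay_s,averaging_s,rapid_desat_pct
#'   Vectors (or lists, to include `NULL`) of candidate values.
#' @return A list of `alarm_settings`.
#' @export
settings_grid <- function(spo2_low = 85, spo2_high = 96, pr_low = 90,
                          pr_high = 200, delay_s = 15, averaging_s = 8,
                          rapid_desat_pct = 10) {
  norm <- function(v) lapply(seq_along(v), function(i) {
    x <- if (is.list(v)) v[[i]] else v[i]
    if (is.null(x) || (length(x) == 1L && is.na(x))) NULL else x
  })
  grid <- expand.grid(i1 = seq_along(norm(spo2_low)),
                      i2 = seq_along(norm(spo2_high)),
                      i3 = seq_along(norm(pr_low)),
                      i4 = seq_along(norm(pr_high)),
                      i5 = seq_along(norm(delay_s)),
                      i6 = seq_along(norm(averaging_s)),
                      i7 = seq_along(norm(rapid_desat_pct)))
  lapply(seq_len(nrow(grid)), function(r) {
    alarm_settings(
      spo2_low = norm(spo2_low)[[grid$i1[r]]],
      spo2_high = norm(spo2_high)[[grid$i2[r]]],
      pr_low = norm(pr_low)[[grid$i3[r]]],
      pr_high = norm(pr_high)[[grid$i4[r]]],
      delay_s = norm(delay_s)[[grid$i5[r]]],
      averaging_s = norm(averaging_s)[[grid$i6[r]]],
      rapid_desat_pct = norm(rapid_desat_pct)[[grid$i7[r]]]
    )
  })
}

#' What-if sweep over alarm settings
#'
#' Re-derives the alarm stream for every trace under every settings point
#' and summarizes counts, densities, out-of-range fractions, and event
#' durations. Deterministic for fixed inputs.
#'
#' @param traces A list of (quality-filtered) `ox_trace` objects, or one
#'   trace.
#' @param grid A list of [alarm_settings()] (see [settings_grid()]).
#' @param config A [segmentation_config()].
#' @return A data frame with one row per settings point.
#' @export
what_if_sweep <- function(traces, grid, config = segmentation_config()) {
  if (inherits(traces, "ox_trace")) traces <- list(traces)
  if (length(grid) == 0L) stop("settings grid must be non-empty")
  if (inherits(grid, "alarm_settings")) grid <- list(grid)
  hours <- sum(vapply(traces, monitored_hours, numeric(1)))
  spo2_pool <- pooled_values(traces, "spo2")
  pr_pool <- pooled_values(traces, "pr")
  rows <- lapply(grid, function(st) {
    ev <- do.call(rbind, lapply(traces, simulate_alarm_stream, settings = st,
                                config = config))
    if (is.null(ev)) ev <- empty_event_table()
    cnt <- vapply(clinical_categories(), function(cc) sum(ev$category == cc),
                  integer(1))
    act <- Reduce(`+`, lapply(traces, alarm_activation_counts, settings = st))
    oor_spo2 <- list(below = mean(spo2_pool < st$spo2_low),
                     above = if (is.null(st$spo2_high)) 0 else
                       mean(spo2_pool > st$spo2_high))
    oor_pr <- list(below = mean(pr_pool < st$pr_low),
                   above = if (is.null(st$pr_high)) 0 else
                     mean(pr_pool > st$pr_high))
    data.frame(
      spo2_low = st$spo2_low,
      spo2_high = st$spo2_high %||% NA_real_,
      pr_low = st$pr_low,
      pr_high = st$pr_high %||% NA_real_,
      delay_s = st$delay_s,
      averaging_s = st$averaging_s,
      rapid_desat_pct = st$rapid_desat_pct,
      n_spo2_low = cnt[["spo2_low"]], n_spo2_high = cnt[["spo2_high"]],
      n_pr_low = cnt[["pr_low"]], n_pr_high = cnt[["pr_high"]],
      n_total = nrow(ev),
      act_spo2_low = act[["spo2_low"]], act_spo2_high = act[["spo2_high"]],
      act_pr_low = act[["pr_low"]], act_pr_high = act[["pr_high"]],
      act_total = sum(act),
      alarms_per_hour = if (hours > 0) nrow(ev) / hours else NA_real_,
      frac_spo2_below = oor_spo2$below, frac_spo2_above = oor_spo2$above,
      frac_pr_below = oor_pr$below, frac_pr_above = oor_pr$above,
      median_duration_s = median_na(ev$duration_s),
      iqr_duration_s = iqr_width(ev$duration_s),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
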