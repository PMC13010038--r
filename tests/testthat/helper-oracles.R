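# Independent reference implementations used as oracles. Both are written
# as plain scalar loops over cells, deliberately sharing no code with the
# package's vectorized implementations.

# Brute-force run-merger: scan the flagged cells of one stream in time
# order, closing an event whenever the silence to the next flagged cell
# exceeds gap_s (exactly gap_s merges).
oracle_merge_cells <- function(t, gap_s, interval = 2) {
  stopifnot(!is.unsorted(t, strictly = TRUE))
  if (length(t) == 0L) {
    return(data.frame(start_t = numeric(0), end_t = numeric(0),
                      active_cell_count = integer(0),
                      duration_s = numeric(0),
                      merged_across_gap = logical(0)))
  }
  groups <- list()
  cur <- t[1]
  for (x in t[-1]) {
    silence <- x - cur[length(cur)] - interval
    if (silence > gap_s) {
      groups[[length(groups) + 1L]] <- cur
      cur <- x
    } else {
      cur <- c(cur, x)
    }
  }
  groups[[length(groups) + 1L]] <- cur
  do.call(rbind, lapply(groups, function(g) {
    data.frame(start_t = g[1], end_t = g[length(g)] + interval,
               active_cell_count = length(g),
               duration_s = length(g) * interval,
               merged_across_gap = any(diff(g) > interval))
  }))
}

# Scalar reference alarm state machine: trailing sample-based averaging,
# strict threshold violation, delay measured in continuously violating
# contiguous cells, rapid-desaturation latch for the low-SpO2 stream.
# Returns indices of asserted cells.
oracle_alarm_cells <- function(t, x, threshold, direction, delay_s,
                               averaging_s, rapid_desat_threshold = NULL,
                               interval = 2) {
  if (is.null(threshold)) return(integer(0))
  n <- length(x)
  k <- averaging_s / interval
  avg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    w <- x[max(1L, i - k + 1L):i]
    w <- w[!is.na(w)]
    if (length(w) > 0L) avg[i] <- mean(w)
  }
  viol <- !is.na(avg) &
    (if (direction == "low") avg < threshold else avg > threshold)
  active <- logical(n)
  run_len <- 0L
  latched <- FALSE
  for (i in seq_len(n)) {
    continues <- i > 1L && viol[i - 1L] && (t[i] - t[i - 1L]) == interval
    if (viol[i]) {
      if (continues) run_len <- run_len + 1L else {
        run_len <- 1L
        latched <- FALSE
      }
      if (!is.null(rapid_desat_threshold) && avg[i] <= rapid_desat_threshold) {
        latched <- TRUE
      }
      active[i] <- latched || (run_len * interval >= delay_s) ||
        delay_s == 0
    } else {
      run_len <- 0L
      latched <- FALSE
    }
  }
  which(active)
}
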