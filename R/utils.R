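# Internal helpers shared across modules.

# Interquartile range reported as a single width (Q3 - Q1), quartiles by
# linear interpolation (stats::quantile type 7).
iqr_width <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  unname(diff(stats::quantile(x, c(0.25, 0.75), type = 7)))
}

median_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  stats::median(x)
}

# Group sorted cell times into events: cells belong to the same event while
# the silence between consecutive cells is <= gap_s. Two cells at times t1 <
# t2 (cells span interval_s seconds) are separated by t2 - t1 - interval_s
# seconds of silence; exactly gap_s merges, strictly more splits.
group_cells_by_gap <- function(t, gap_s, interval_s = 2) {
  if (length(t) == 0L) return(integer(0))
  cumsum(c(TRUE, diff(t) - interval_s > gap_s))
}

# Run-value sampler: draws runs of integer values with value-dependent
# geometric run lengths until at least n cells are produced. The stationary
# cell-level marginal is proportional to prob[v] * mean_len[v] when runs are
# drawn independently; callers that target a cell marginal pi should pass
# prob = pi / mean_len (renormalized).
sample_run_values <- function(n, values, prob, mean_len) {
  stopifnot(length(values) == length(prob), all(prob >= 0), all(mean_len >= 1))
  prob <- prob / sum(prob)
  if (n <= 0L) return(numeric(0))
  mean_run <- sum(prob * mean_len)
  out <- NULL
  got <- 0L
  while (got < n) {
    m <- max(16L, ceiling((n - got) / mean_run * 1.4) + 8L)
    idx <- sample.int(length(values), m, replace = TRUE, prob = prob)
    lens <- stats::rgeom(m, prob = 1 / mean_len[idx]) + 1L
    piece <- rep(values[idx], lens)
    out <- c(out, piece)
    got <- length(out)
  }
  out[seq_len(n)]
}

# Truncated draws via inverse-CDF so truncation never distorts the RNG stream
# length (one uniform per draw).
rnorm_trunc <- function(n, mean, sd, lower, upper) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pa, pb), mean, sd)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  pa <- stats::plnorm(lower, meanlog, sdlog)
  pb <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, pa, pb), meanlog, sdlog)
}

# Minimum across groups, returning +Inf for groups with no finite entries.
group_min <- function(x, g) {
  out <- rep(Inf, max(g, 0L))
  agg <- tapply(x, g, min)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `fn()` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
withr_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
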