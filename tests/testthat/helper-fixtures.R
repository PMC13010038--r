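# In-code fixtures: all test traces are built programmatically.

make_samples <- function(n, t = seq(0, by = 2, length.out = n),
                         spo2 = rep(92, n), pr = rep(150, n),
                         pi = rep(1.5, n), siq = rep("ok", n),
                         events = rep("", n)) {
  data.frame(t = t, spo2 = spo2, pr = pr, pi = pi, siq = siq,
             events = events, stringsAsFactors = FALSE)
}

make_trace <- function(n = 20, ..., neonate_id = "T01", device_id = "D01",
                       validate = TRUE) {
  ox_trace(make_samples(n, ...), neonate_id, device_id, validate = validate)
}

# Trace whose events column flags the given cells with a clinical alarm
# token; `cells` is a list keyed by category.
annotate_cells <- function(trace, cells,
                           tokens = c(spo2_low = "SpO2 Low Alarm",
                                      spo2_high = "SpO2 High Alarm",
                                      pr_low = "PR Low Alarm",
                                      pr_high = "PR High Alarm",
                                      system = "Sensor Off")) {
  ev <- trace$samples$events
  for (cat in names(cells)) {
    idx <- cells[[cat]]
    ev[idx] <- ifelse(nzchar(ev[idx]), paste(ev[idx], tokens[[cat]], sep = ";"),
                      tokens[[cat]])
  }
  trace$samples$events <- ev
  trace
}

# Random annotated trace with clumpy per-category flags, random audible /
# silenced tokens and occasional grid gaps; used by the segmentation
# oracle-equivalence and conservation properties.
random_annotated_trace <- function(max_cells = 200, p_gap = 0.08) {
  n <- sample(20:max_cells, 1)
  steps <- sample(c(2, 2, 2, 2, 4, 8, 28, 30, 32, 40), n - 1, replace = TRUE,
                  prob = c(rep((1 - p_gap) / 4, 4), rep(p_gap / 6, 6)))
  t <- cumsum(c(0, steps))
  ev <- rep("", n)
  for (cat in c("spo2_low", "spo2_high", "pr_low", "pr_high")) {
    state <- FALSE
    flag <- logical(n)
    for (i in seq_len(n)) {
      state <- if (state) runif(1) < 0.75 else runif(1) < 0.12
      flag[i] <- state
    }
    base <- c(spo2_low = "SpO2 Low Alarm", spo2_high = "SpO2 High Alarm",
              pr_low = "PR Low Alarm", pr_high = "PR High Alarm")[[cat]]
    tok <- ifelse(runif(n) < 0.7, base, paste0(base, " (Silenced)"))
    idx <- which(flag)
    ev[idx] <- ifelse(nzchar(ev[idx]), paste(ev[idx], tok[idx], sep = ";"),
                      tok[idx])
  }
  make_trace(n, t = t, events = ev)
}

# Random vitals trace (values only, no annotations) for alarm-logic
# properties; includes NAs and occasional grid gaps.
random_vitals_trace <- function(max_cells = 200) {
  n <- sample(30:max_cells, 1)
  steps <- sample(c(2, 2, 2, 2, 2, 4, 6), n - 1, replace = TRUE)
  t <- cumsum(c(0, steps))
  spo2 <- sample(c(70:100, NA), n, replace = TRUE,
                 prob = c(rep(1, 15), rep(4, 16), 3))
  pr <- sample(c(60:230, NA), n, replace = TRUE)
  make_trace(n, t = t, spo2 = spo2, pr = pr)
}

# Small synthetic cohort spec for fast tests: short traces, optional
# overrides for rates and artifacts.
mini_spec <- function(n_neonates = 2, seed = 99, median_days = 0.06,
                      artifact_rate = NULL, desat_rate = NULL,
                      high_rate = NULL, min_gap_s = NULL,
                      heterogeneity = NULL, siq_rate = NULL) {
  spec <- default_calibration(n_neonates = n_neonates, seed = seed)
  spec$duration <- list(median_days = median_days, sdlog = 0.3,
                        min_days = median_days / 2, max_days = median_days * 2)
  spec$artifact$mean_s <- 120
  if (!is.null(artifact_rate)) spec$artifact$rate_per_h <- artifact_rate
  if (!is.null(desat_rate)) spec$spo2$desat_rate_per_h <- desat_rate
  if (!is.null(high_rate)) spec$spo2$high_rate_per_h <- high_rate
  if (!is.null(min_gap_s)) spec$spo2$min_gap_s <- min_gap_s
  if (!is.null(heterogeneity)) {
    spec$spo2$rate_heterogeneity_sdlog <- heterogeneity
    spec$pr$rate_heterogeneity_sdlog <- heterogeneity
  }
  if (!is.null(siq_rate)) spec$siq$burst_rate_per_h <- siq_rate
  spec
}
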