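#' Synthetic cohort specification
#'
#' Parameters of the synthetic neonatal vitals generator. A cohort is a set
#' of per-neonate 0.5 Hz traces built from:
#'
#' * a sticky semi-Markov SpO2 baseline over 85-96% (integer values, run
#'   lengths geometric with value-dependent means, heavy mass at 96%);
#' * high-saturation excursions into 97-100% (a mixture of brief swings and
#'   rare prolonged high-saturation periods, as seen on supplemental
#'   oxygen) and desaturation episodes below 85% (many brief shallow dips,
#'   fewer sustained deep events) placed by an alternating renewal process;
#' * a pulse-rate baseline (rounded truncated-normal run process) with
#'   bradycardia and tachycardia episode overlays, bradycardias partly
#'   coupled to deep desaturations;
#' * artifact segments (sensor off, low perfusion, cable disconnect)
#'   producing invalid entries, noisy readings and low SIQ;
#' * device alarm annotations computed by the package's own alarm state
#'   machine under `settings`, so annotations are reproducible from the
#'   trace by [simulate_alarm_stream()].
#'
#' All rates are per monitored hour; dwell times are `min + Exp(mean)`
#' seconds. Per-neonate heterogeneity multiplies episode rates by lognormal
#' factors (unit mean, `rate_heterogeneity_sdlog`) and shifts the PR
#' baseline by a normal offset (`pr$between_sd`).
#'
#' @param n_neonates Number of neonates.
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   byte for byte.
#' @param duration,spo2,pr,artifact,siq Component parameter lists; see
#'   [default_calibration()] for the shipped values.
#' @param audible_p Probability that an annotated alarm event is audible
#'   (otherwise silenced, i.e. visual-only).
#' @param settings [alarm_settings()] used for the embedded annotations.
#' @param gap_s Gap rule used when annotating events.
#' @return A list of class `cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_neonates, seed, duration, spo2, pr,
                                  artifact, siq, audible_p = 0.72,
                                  settings = alarm_settings(), gap_s = 30) {
  spec <- structure(list(
    n_neonates = as.integer(n_neonates), seed = as.integer(seed),
    duration = duration, spo2 = spo2, pr = pr, artifact = artifact,
    siq = siq, audible_p = audible_p, settings = settings, gap_s = gap_s
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_neonates >= 1L, is.finite(spec$seed))
  d <- spec$duration
  stopifnot(d$min_days > 0, d$max_days >= d$min_days, d$median_days > 0)
  sp <- spec$spo2
  stopifnot(all(sp$inrange_marginal >= 0),
            abs(sum(sp$inrange_marginal) - 1) < 1e-8,
            all(sp$inrange_mean_len >= 1),
            length(sp$inrange_marginal) == length(sp$inrange_values),
            all(sp$high_marginal >= 0), abs(sum(sp$high_marginal) - 1) < 1e-8,
            all(sp$nadir_probs >= 0), abs(sum(sp$nadir_probs) - 1) < 1e-8,
            sp$high_rate_per_h >= 0, sp$desat_rate_per_h >= 0,
            sp$min_gap_s >= 2)
  for (f in c("high_short_min_s", "high_short_mean_s", "high_long_min_s",
              "high_long_mean_s", "desat_brief_min_s", "desat_brief_mean_s",
              "desat_sust_min_s", "desat_sust_mean_s")) {
    if (is.null(sp[[f]]) || !is.finite(sp[[f]]) || sp[[f]] < 0) {
      stop("spo2$", f, " must be a finite non-negative number")
    }
  }
  lam_tot <- sp$high_rate_per_h + sp$desat_rate_per_h
  if (lam_tot > 0) {
    e_mix <- (sp$high_rate_per_h * high_dwell_mean(sp) +
                sp$desat_rate_per_h * desat_dwell_mean(sp)) / lam_tot
    gap_mean <- 3600 / lam_tot - e_mix
    if (gap_mean <= sp$min_gap_s) {
      stop("infeasible spec: episode load leaves no room for baseline ",
           "(mean inter-episode gap ", round(gap_mean, 1), " s <= min gap)")
    }
  }
  a <- spec$artifact
  stopifnot(a$rate_per_h >= 0, a$mean_s > 0,
            abs(sum(a$type_probs) - 1) < 1e-8)
  if (a$rate_per_h > 0 && (a$min_s + a$mean_s) / 86400 > spec$duration$min_days) {
    stop("infeasible spec: typical artifact segment longer than the ",
         "shortest monitoring duration")
  }
  stopifnot(spec$audible_p >= 0, spec$audible_p <= 1)
  invisible(spec)
}

high_dwell_mean <- function(sp) {
  sp$high_short_p * (sp$high_short_min_s + sp$high_short_mean_s) +
    (1 - sp$high_short_p) * (sp$high_long_min_s + sp$high_long_mean_s)
}

desat_dwell_mean <- function(sp) {
  sp$desat_brief_p * (sp$desat_brief_min_s + sp$desat_brief_mean_s) +
    (1 - sp$desat_brief_p) * (sp$desat_sust_min_s + sp$desat_sust_mean_s)
}

# Discretized truncated-normal pmf on integers lo..hi: the law of
# round(X) for X ~ N(mu, sd) truncated to (lo, hi). When tau > 0 the pmf is
# averaged over a normal location shift (between-neonate spread), using
# mid-quantile nodes.
disc_trunc_pmf <- function(mu, sd, lo, hi, tau = 0, nodes = 21L) {
  v <- lo:hi
  shift <- if (tau > 0) stats::qnorm((seq_len(nodes) - 0.5) / nodes) * tau
  else 0
  p <- rep(0, length(v))
  for (dlt in shift) {
    z <- stats::pnorm(hi, mu + dlt, sd) - stats::pnorm(lo, mu + dlt, sd)
    up <- pmin(v + 0.5, hi)
    dn <- pmax(v - 0.5, lo)
    p <- p + (stats::pnorm(up, mu + dlt, sd) - stats::pnorm(dn, mu + dlt, sd)) / z
  }
  list(v = v, p = p / length(shift))
}

# Solve for the PR baseline location/scale and the tachycardia fraction so
# that the pooled PR marginal (baseline + bradycardia + tachycardia
# overlays) matches the target mean, SD and tail masses. Deterministic
# moment-matching on the exact discrete mixture.
solve_pr_parameters <- function(target_mean, target_sd, frac_below,
                                frac_above, brady, tachy, tau,
                                baseline_lo = 100, baseline_hi = 200) {
  pmf_b <- disc_trunc_pmf(brady$level_mean, brady$level_sd,
                          brady$level_lo, brady$level_hi)
  pmf_t <- disc_trunc_pmf(tachy$level_mean, tachy$level_sd,
                          tachy$level_lo, tachy$level_hi)
  p_le89 <- sum(pmf_b$p[pmf_b$v <= 89])
  p_gt200 <- sum(pmf_t$p[pmf_t$v >= 201])
  f_b <- frac_below / p_le89
  f_t <- frac_above / p_gt200
  m_b <- sum(pmf_b$v * pmf_b$p)
  m2_b <- sum(pmf_b$v^2 * pmf_b$p)
  m_t <- sum(pmf_t$v * pmf_t$p)
  m2_t <- sum(pmf_t$v^2 * pmf_t$p)
  f0 <- 1 - f_b - f_t
  mean0 <- (target_mean - f_b * m_b - f_t * m_t) / f0
  m2_target <- target_sd^2 + target_mean^2
  m2_0 <- (m2_target - f_b * m2_b - f_t * m2_t) / f0
  sd0 <- sqrt(m2_0 - mean0^2)
  # fixed point: find (mu, sigma) whose truncated/rounded/shifted marginal
  # has moments (mean0, sd0)
  mu <- mean0
  sig <- sd0
  for (i in 1:80) {
    pmf <- disc_trunc_pmf(mu, sig, baseline_lo, baseline_hi, tau = tau)
    m_act <- sum(pmf$v * pmf$p)
    s_act <- sqrt(sum(pmf$v^2 * pmf$p) - m_act^2)
    mu <- mu + (mean0 - m_act)
    sig <- sig * sd0 / s_act
  }
  list(mu = mu, sigma = sig, f_brady = f_b, f_tachy = f_t)
}

#' Default-calibrated synthetic cohort specification
#'
#' Returns the shipped cohort spec whose emergent pooled statistics are
#' calibrated to the study unit's printed summaries. The calibration is
#' arithmetic on the printed pooled statistics, not direct assignment of the
#' statistics themselves: episode *rates* are derived from target time
#' fractions divided by mean dwell times, the desaturation depth law from
#' the relative tail masses below 85% and 80.2%, and the PR baseline by
#' deterministic moment matching of the full baseline-plus-episodes mixture
#' (see the methods vignette for the derivations). Durations are scaled
#' down about 5.6-fold from the unit's monitoring durations (median 2
#' simulated days, range 2.9 hours to 7.3 days) so a 49-neonate cohort
#' stays desk-sized; rates and marginals are per-hour quantities and are
#' unaffected by the scaling.
#'
#' @param n_neonates Cohort size (default 49).
#' @param seed Integer seed (default 20211).
#' @return A `cohort_spec`.
#' @export
default_calibration <- function(n_neonates = 49, seed = 20211) {
  # printed pooled SpO2 statistics driving the calibration
  pct_below_85 <- 5.78     # % of valid SpO2 samples below the lower threshold
  pct_outside <- 50        # % outside the 85-96% range
  pct_below_802 <- 3.4     # % below a hypothetical 80.2% threshold
  high_split <- c(`97` = 0.22, `98` = 0.22, `99` = 0.20, `100` = 0.36)

  f_low <- pct_below_85 / 100
  f_high <- (pct_outside - pct_below_85) / 100
  f_base <- 1 - f_low - f_high

  # in-range cell marginal over 85..96 (conditional on being in range):
  # sticky near 93-96 with a point mass at 96 large enough that the pooled
  # median sits at 96 with margin (P(<=95) ~ 0.44) and Q1 ~ 93.
  pi_in <- c(0.016, 0.020, 0.024, 0.032, 0.044, 0.060,
             0.080, 0.104, 0.120, 0.130, 0.130, 0.240)
  mean_len <- c(rep(3, 8), 6, 6, 6, 10)

  # desaturation depth law: mass below 80.2% vs 85% fixes P(nadir <= 80);
  # the deep share (<= 75%, the rapid-desaturation zone at default
  # settings) and the within-band shapes are realism choices.
  below80_share <- pct_below_802 / pct_below_85
  deep_share <- 0.208
  shape_shallow <- c(`81` = 1, `82` = 1, `83` = 1, `84` = 1)
  shape_mid <- c(`76` = 1, `77` = 1.2, `78` = 1.6, `79` = 1.8, `80` = 2)
  shape_deep <- c(`70` = 0.4, `71` = 0.7, `72` = 1.2, `73` = 1.9,
                  `74` = 2.4, `75` = 3.3)
  nadir_probs <- c(
    shape_deep / sum(shape_deep) * deep_share,
    shape_mid / sum(shape_mid) * (below80_share - deep_share),
    shape_shallow / sum(shape_shallow) * (1 - below80_share)
  )

  # dwell-time mixtures (seconds); the desaturation rate follows from the
  # below-85 time fraction, the long-high mean dwell from the above-96 time
  # fraction at the chosen high-excursion rate.
  spo2 <- list(
    inrange_values = 85:96,
    inrange_marginal = pi_in / sum(pi_in),
    inrange_mean_len = mean_len,
    high_values = 97:100,
    high_marginal = as.numeric(high_split),
    high_mean_len = rep(5, 4),
    high_rate_per_h = 6.8,
    high_short_p = 0.90,
    high_short_min_s = 10, high_short_mean_s = 18,
    high_long_min_s = 60, high_long_mean_s = NA_real_,
    desat_rate_per_h = NA_real_,
    desat_brief_p = 0.55,
    desat_brief_min_s = 6, desat_brief_mean_s = 8,
    desat_sust_min_s = 16, desat_sust_mean_s = 36,
    nadir_values = as.integer(names(nadir_probs)),
    nadir_probs = as.numeric(nadir_probs),
    min_gap_s = 4,
    rate_heterogeneity_sdlog = 0.10
  )
  e_desat <- desat_dwell_mean(spo2)
  spo2$desat_rate_per_h <- f_low * 3600 / e_desat
  e_high_target <- f_high * 3600 / spo2$high_rate_per_h
  short_part <- spo2$high_short_p * (spo2$high_short_min_s + spo2$high_short_mean_s)
  long_mean_total <- (e_high_target - short_part) / (1 - spo2$high_short_p)
  spo2$high_long_mean_s <- long_mean_total - spo2$high_long_min_s
  if (spo2$high_long_mean_s <= 0) stop("infeasible high-excursion calibration")

  # printed pooled PR statistics
  brady <- list(level_mean = 80, level_sd = 7, level_lo = 55, level_hi = 95,
                min_s = 10, mean_s = 20)
  tachy <- list(level_mean = 206, level_sd = 6, level_lo = 195, level_hi = 235,
                min_s = 10, mean_s = 20)
  sol <- solve_pr_parameters(
    target_mean = 158, target_sd = 19.87,
    frac_below = 0.0092, frac_above = 0.0108,
    brady = brady, tachy = tachy, tau = 2.5
  )
  couple_p <- 0.25
  deep_threshold <- 85 - 10
  lam_deep <- spo2$desat_rate_per_h *
    sum(nadir_probs[as.integer(names(nadir_probs)) <= deep_threshold])
  brady_dwell <- brady$min_s + brady$mean_s
  tachy_dwell <- tachy$min_s + tachy$mean_s
  pr <- list(
    baseline_mean = sol$mu, baseline_sd = sol$sigma,
    baseline_lo = 100, baseline_hi = 200,
    baseline_mean_len = 5,
    between_sd = 2.5,
    brady = brady, tachy = tachy,
    brady_rate_per_h = max(0, sol$f_brady * 3600 / brady_dwell -
                             couple_p * lam_deep),
    brady_couple_p = couple_p,
    tachy_rate_per_h = sol$f_tachy * 3600 / tachy_dwell,
    rate_heterogeneity_sdlog = 0.10
  )

  synthetic_cohort_spec(
    n_neonates = n_neonates, seed = seed,
    duration = list(median_days = 2.0, sdlog = 0.8,
                    min_days = 16 / 24 / 5.6, max_days = 41 / 5.6),
    spo2 = spo2, pr = pr,
    artifact = list(
      rate_per_h = 1.33, min_s = 30, mean_s = 240,
      type_probs = c(sensor_off = 0.5, low_perfusion = 0.4, cable = 0.1),
      null_p_spo2 = c(sensor_off = 0.95, low_perfusion = 0.45, cable = 0.95),
      null_p_pr = c(sensor_off = 0.93, low_perfusion = 0.44, cable = 0.95),
      noise_sd_spo2 = 8, noise_sd_pr = 25
    ),
    siq = list(burst_rate_per_h = 2, burst_mean_cells = 3),
    audible_p = 0.72,
    settings = alarm_settings(),
    gap_s = 30
  )
}

artifact_token <- function(type) {
  c(sensor_off = "Sensor Off", low_perfusion = "Low Perfusion",
    cable = "Cable Disconnect")[[type]]
}

# Draw an alternating gap/episode timeline in cells. Returns a data frame of
# episodes (start cell, length in cells, type and value columns filled by
# the caller) covering [1, n_cells].
draw_episode_timeline <- function(n_cells, lam_high, lam_desat, sp) {
  lam_tot <- lam_high + lam_desat
  if (lam_tot <= 0) {
    return(data.frame(start = integer(0), len = integer(0),
                      is_high = logical(0), dwell_s = numeric(0)))
  }
  e_mix <- (lam_high * high_dwell_mean(sp) + lam_desat * desat_dwell_mean(sp)) /
    lam_tot
  gap_mean <- 3600 / lam_tot - e_mix
  if (gap_mean <= sp$min_gap_s) {
    stop("infeasible spec: episode load leaves no room for baseline")
  }
  total_s <- n_cells * 2
  starts <- integer(0); lens <- integer(0); is_high <- logical(0)
  dwells <- numeric(0)
  pos <- 0L  # last used cell
  p_high <- lam_high / lam_tot
  e_cycle <- gap_mean + e_mix
  repeat {
    m <- max(16L, ceiling((total_s - pos * 2) / e_cycle * 1.3) + 8L)
    gap_s <- sp$min_gap_s + stats::rexp(m, 1 / (gap_mean - sp$min_gap_s))
    hi <- stats::runif(m) < p_high
    u <- stats::runif(m)
    dwell_s <- ifelse(
      hi,
      ifelse(u < sp$high_short_p,
             sp$high_short_min_s + stats::rexp(m, 1 / sp$high_short_mean_s),
             sp$high_long_min_s + stats::rexp(m, 1 / sp$high_long_mean_s)),
      ifelse(u < sp$desat_brief_p,
             sp$desat_brief_min_s + stats::rexp(m, 1 / sp$desat_brief_mean_s),
             sp$desat_sust_min_s + stats::rexp(m, 1 / sp$desat_sust_mean_s))
    )
    gap_c <- pmax(1L, as.integer(round(gap_s / 2)))
    len_c <- pmax(1L, as.integer(round(dwell_s / 2)))
    for (j in seq_len(m)) {
      s <- pos + gap_c[j] + 1L
      if (s > n_cells) {
        pos <- n_cells
        break
      }
      e <- min(s + len_c[j] - 1L, n_cells)
      starts <- c(starts, s); lens <- c(lens, e - s + 1L)
      is_high <- c(is_high, hi[j]); dwells <- c(dwells, dwell_s[j])
      pos <- e
    }
    if (pos >= n_cells) break
  }
  data.frame(start = starts, len = lens, is_high = is_high,
             dwell_s = dwells)
}

# Baseline run process with continuous (normal) run values.
sample_normal_runs <- function(n, mu, sd, lo, hi, mean_len) {
  out <- NULL
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) / mean_len * 1.4) + 8L)
    lens <- stats::rgeom(m, 1 / mean_len) + 1L
    vals <- round(rnorm_trunc(m, mu, sd, lo, hi))
    out <- c(out, rep(vals, lens))
  }
  out[seq_len(n)]
}

# Poisson episode overlay: uniform starts, min+Exp dwells, per-episode
# levels; overlapping episodes (after sorting) are dropped.
draw_overlay_episodes <- function(n_cells, rate_per_h, min_s, mean_s,
                                  level_mean, level_sd, level_lo, level_hi) {
  hours <- n_cells * 2 / 3600
  k <- stats::rpois(1, rate_per_h * hours)
  if (k == 0L) {
    return(data.frame(start = integer(0), len = integer(0),
                      level = numeric(0)))
  }
  start <- sort(sample.int(n_cells, k, replace = TRUE))
  len <- pmax(1L, as.integer(round((min_s + stats::rexp(k, 1 / mean_s)) / 2)))
  level <- round(rnorm_trunc(k, level_mean, level_sd, level_lo, level_hi))
  keep_disjoint(data.frame(start = start, len = len, level = level), n_cells)
}

keep_disjoint <- function(df, n_cells) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start), , drop = FALSE]
  keep <- logical(nrow(df))
  last_end <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- min(df$start[i] + df$len[i] - 1L, n_cells)
      df$len[i] <- last_end - df$start[i] + 1L
    }
  }
  df[keep, , drop = FALSE]
}

segment_cells <- function(start, len) {
  if (length(start) == 0L) return(integer(0))
  unlist(mapply(function(s, l) seq.int(s, s + l - 1L), start, len,
                SIMPLIFY = FALSE), use.names = FALSE)
}

append_tokens <- function(events, idx, token, sep = ";") {
  if (length(idx) == 0L) return(events)
  events[idx] <- ifelse(nzchar(events[idx]),
                        paste(events[idx], token, sep = sep), token)
  events
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Generate one neonate's trace plus ground-truth records. RNG draws happen
# in a fixed order so the per-neonate seed fully determines the output.
generate_neonate <- function(spec, neonate_id, device_id, seed) {
  set.seed(seed)
  sp <- spec$spo2
  d <- spec$duration
  dur_days <- rlnorm_trunc(1, log(d$median_days), d$sdlog,
                           d$min_days, d$max_days)
  n <- max(64L, as.integer(round(dur_days * 86400 / 2)))
  tt <- seq(0, by = 2, length.out = n)
  hours <- n * 2 / 3600

  sdl <- sp$rate_heterogeneity_sdlog
  r_high <- stats::rlnorm(1, -sdl^2 / 2, sdl)
  r_desat <- stats::rlnorm(1, -sdl^2 / 2, sdl)
  sdl_pr <- spec$pr$rate_heterogeneity_sdlog
  r_brady <- stats::rlnorm(1, -sdl_pr^2 / 2, sdl_pr)
  r_tachy <- stats::rlnorm(1, -sdl_pr^2 / 2, sdl_pr)
  pr_shift <- stats::rnorm(1, 0, spec$pr$between_sd)

  # --- SpO2: baseline + excursion overlay --------------------------------
  spo2 <- sample_run_values(n, sp$inrange_values,
                            sp$inrange_marginal / sp$inrange_mean_len,
                            sp$inrange_mean_len)
  epi <- draw_episode_timeline(n, sp$high_rate_per_h * r_high,
                               sp$desat_rate_per_h * r_desat, sp)
  nadir <- rep(NA_real_, nrow(epi))
  if (any(!epi$is_high)) {
    nadir[!epi$is_high] <- sample(sp$nadir_values, sum(!epi$is_high),
                                  replace = TRUE, prob = sp$nadir_probs)
  }
  hi_cells <- segment_cells(epi$start[epi$is_high], epi$len[epi$is_high])
  if (length(hi_cells) > 0L) {
    spo2[hi_cells] <- sample_run_values(length(hi_cells), sp$high_values,
                                        sp$high_marginal / sp$high_mean_len,
                                        sp$high_mean_len)
  }
  if (any(!epi$is_high)) {
    lo <- which(!epi$is_high)
    spo2[segment_cells(epi$start[lo], epi$len[lo])] <-
      rep(nadir[lo], epi$len[lo])
  }

  # --- PR: baseline + bradycardia/tachycardia overlays -------------------
  prp <- spec$pr
  pr <- sample_normal_runs(n, prp$baseline_mean + pr_shift, prp$baseline_sd,
                           prp$baseline_lo, prp$baseline_hi,
                           prp$baseline_mean_len)
  brady <- draw_overlay_episodes(n, prp$brady_rate_per_h * r_brady,
                                 prp$brady$min_s, prp$brady$mean_s,
                                 prp$brady$level_mean, prp$brady$level_sd,
                                 prp$brady$level_lo, prp$brady$level_hi)
  deep_thr <- spec$settings$spo2_low - spec$settings$rapid_desat_pct
  deep_idx <- which(!epi$is_high & nadir <= deep_thr)
  if (length(deep_idx) > 0L) {
    pick <- deep_idx[stats::runif(length(deep_idx)) < prp$brady_couple_p]
    if (length(pick) > 0L) {
      k <- length(pick)
      coupled <- data.frame(
        start = pmin(n, epi$start[pick] + sample.int(4L, k, replace = TRUE) - 1L),
        len = pmax(1L, as.integer(round(
          (prp$brady$min_s + stats::rexp(k, 1 / prp$brady$mean_s)) / 2))),
        level = round(rnorm_trunc(k, prp$brady$level_mean, prp$brady$level_sd,
                                  prp$brady$level_lo, prp$brady$level_hi))
      )
      brady <- keep_disjoint(rbind(brady, coupled), n)
    }
  }
  tachy <- draw_overlay_episodes(n, prp$tachy_rate_per_h * r_tachy,
                                 prp$tachy$min_s, prp$tachy$mean_s,
                                 prp$tachy$level_mean, prp$tachy$level_sd,
                                 prp$tachy$level_lo, prp$tachy$level_hi)
  # tachycardias yield to bradycardias on overlap (brady applied last)
  pr[segment_cells(tachy$start, tachy$len)] <- rep(tachy$level, tachy$len)
  pr[segment_cells(brady$start, brady$len)] <- rep(brady$level, brady$len)

  # --- perfusion index ---------------------------------------------------
  pi_v <- round(pmin(pmax(
    exp(sample_normal_runs(n, log(1.4) * 10, 4, -5, 30, 30) / 10), 0.3), 20), 2)

  # --- artifacts ---------------------------------------------------------
  art <- spec$artifact
  a_hours <- hours
  a_k <- stats::rpois(1, art$rate_per_h * a_hours)
  artifacts <- data.frame(start = integer(0), len = integer(0),
                          type = character(0), stringsAsFactors = FALSE)
  if (a_k > 0L) {
    a_start <- sort(sample.int(n, a_k, replace = TRUE))
    a_len <- pmax(1L, as.integer(round(
      (art$min_s + stats::rexp(a_k, 1 / art$mean_s)) / 2)))
    a_type <- sample(names(art$type_probs), a_k, replace = TRUE,
                     prob = art$type_probs)
    artifacts <- keep_disjoint(
      data.frame(start = a_start, len = a_len, level = seq_len(a_k)), n)
    artifacts$type <- a_type[artifacts$level]
    artifacts$level <- NULL
  }

  events <- character(n)
  siq <- rep("ok", n)
  for (i in seq_len(nrow(artifacts))) {
    cells <- seq.int(artifacts$start[i],
                     artifacts$start[i] + artifacts$len[i] - 1L)
    type <- artifacts$type[i]
    events <- append_tokens(events, cells, artifact_token(type))
    null_spo2 <- stats::runif(length(cells)) < art$null_p_spo2[[type]]
    null_pr <- stats::runif(length(cells)) < art$null_p_pr[[type]]
    noisy <- cells[!null_spo2]
    spo2[noisy] <- clamp(round(spo2[noisy] +
                                 stats::rnorm(length(noisy), 0, art$noise_sd_spo2)),
                         50, 100)
    noisy_pr <- cells[!null_pr]
    pr[noisy_pr] <- clamp(round(pr[noisy_pr] +
                                  stats::rnorm(length(noisy_pr), 0, art$noise_sd_pr)),
                          30, 250)
    spo2[cells[null_spo2]] <- NA_real_
    pr[cells[null_pr]] <- NA_real_
    events <- append_tokens(events, cells[null_spo2], invalid_spo2_token())
    events <- append_tokens(events, cells[null_pr], invalid_pr_token())
    if (type == "low_perfusion") {
      pi_v[cells] <- round(stats::runif(length(cells), 0.05, 0.3), 2)
      siq[cells] <- "low"
    } else {
      pi_v[cells] <- NA_real_
    }
  }

  sq <- spec$siq
  s_k <- stats::rpois(1, sq$burst_rate_per_h * hours)
  if (s_k > 0L) {
    s_start <- sample.int(n, s_k, replace = TRUE)
    s_len <- stats::rgeom(s_k, 1 / sq$burst_mean_cells) + 1L
    siq[segment_cells(pmin(s_start, n),
                      pmin(s_len, n - s_start + 1L))] <- "low"
  }

  # --- device alarm annotations (own alarm logic, default settings) ------
  samples <- data.frame(t = tt, spo2 = spo2, pr = pr, pi = pi_v,
                        siq = siq, events = events, stringsAsFactors = FALSE)
  trace <- ox_trace(samples, neonate_id, device_id, validate = FALSE)
  act <- alarm_active_cells(trace, spec$settings)
  base_token <- c(spo2_low = "SpO2 Low Alarm", spo2_high = "SpO2 High Alarm",
                  pr_low = "PR Low Alarm", pr_high = "PR High Alarm")
  alarm_rows <- list()
  for (cat in names(act)) {
    idx <- act[[cat]]
    if (length(idx) == 0L) next
    ev <- events_from_cells(tt[idx], spec$gap_s, 2)
    audible <- stats::runif(nrow(ev)) < spec$audible_p
    grp <- group_cells_by_gap(tt[idx], spec$gap_s, 2)
    tok <- ifelse(audible, base_token[[cat]],
                  paste0(base_token[[cat]], " (Silenced)"))
    cell_tok <- tok[grp]
    for (tk in unique(cell_tok)) {
      events <- append_tokens(events, idx[cell_tok == tk], tk)
    }
    ev$category <- cat
    ev$audible <- audible
    ev$modality <- ifelse(audible, "audio_visual", "visual")
    alarm_rows[[cat]] <- ev
  }
  trace$samples$events <- events

  alarm_events <- do.call(rbind, alarm_rows)
  if (is.null(alarm_events)) {
    alarm_events <- cbind(empty_event_table(), audible = logical(0))
  } else {
    alarm_events$neonate_id <- neonate_id
    alarm_events <- alarm_events[order(alarm_events$start_t, alarm_events$category),
                                 c("neonate_id", "category", "modality",
                                   "start_t", "end_t", "active_cell_count",
                                   "duration_s", "merged_across_gap", "audible")]
    rownames(alarm_events) <- NULL
  }

  episodes <- data.frame(
    neonate_id = rep(neonate_id, nrow(epi)),
    type = ifelse(epi$is_high, "spo2_high", "desat"),
    start_t = tt[epi$start],
    dwell_s = epi$len * 2,
    value = ifelse(epi$is_high, NA_real_, nadir),
    stringsAsFactors = FALSE
  )
  if (nrow(brady) > 0L) {
    episodes <- rbind(episodes, data.frame(
      neonate_id = neonate_id, type = "brady", start_t = tt[brady$start],
      dwell_s = brady$len * 2, value = brady$level, stringsAsFactors = FALSE))
  }
  if (nrow(tachy) > 0L) {
    episodes <- rbind(episodes, data.frame(
      neonate_id = neonate_id, type = "tachy", start_t = tt[tachy$start],
      dwell_s = tachy$len * 2, value = tachy$level, stringsAsFactors = FALSE))
  }
  artifact_truth <- if (nrow(artifacts) > 0L) {
    data.frame(neonate_id = neonate_id, type = artifacts$type,
               start_t = tt[artifacts$start], dwell_s = artifacts$len * 2,
               stringsAsFactors = FALSE)
  } else {
    data.frame(neonate_id = character(0), type = character(0),
               start_t = numeric(0), dwell_s = numeric(0),
               stringsAsFactors = FALSE)
  }

  list(trace = trace, episodes = episodes, artifacts = artifact_truth,
       alarm_events = alarm_events)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds `spec$n_neonates` traces plus ground-truth records: the planted
#' clinical episodes (type, onset, dwell, depth/level), the artifact
#' segments, and the exact alarm annotation events implied by the device
#' settings (computed with the package's own alarm state machine, so
#' re-running [simulate_alarm_stream()] with the same settings on a raw
#' generated trace reproduces them). Per-neonate seeds are derived from
#' `spec$seed`, so the same spec yields a byte-identical cohort on every
#' run.
#'
#' @param spec A `cohort_spec` (see [default_calibration()]).
#' @return A list of class `synthetic_cohort` with elements `traces` (list
#'   of `ox_trace`), `truth` (list with `episodes`, `artifacts`,
#'   `alarm_events` data frames), and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, spec$n_neonates)
  ids <- sprintf("N%02d", seq_len(spec$n_neonates))
  devs <- sprintf("OXI-%02d", (seq_len(spec$n_neonates) - 1L) %% 10L + 1L)
  res <- lapply(seq_len(spec$n_neonates), function(i) {
    generate_neonate(spec, ids[i], devs[i], seeds[i])
  })
  traces <- lapply(res, `[[`, "trace")
  names(traces) <- ids
  truth <- list(
    episodes = do.call(rbind, lapply(res, `[[`, "episodes")),
    artifacts = do.call(rbind, lapply(res, `[[`, "artifacts")),
    alarm_events = do.call(rbind, lapply(res, `[[`, "alarm_events"))
  )
  rownames(truth$episodes) <- rownames(truth$artifacts) <-
    rownames(truth$alarm_events) <- NULL
  structure(list(traces = traces, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk
#'
#' Emits one trace CSV per neonate in the documented dialect plus
#' ground-truth sidecar files (`truth_episodes.csv`, `truth_artifacts.csv`,
#' `truth_alarm_events.csv`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param dialect Trace CSV dialect.
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = trace_dialect()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort$traces, function(tr) {
    p <- file.path(dir, paste0(tr$neonate_id, ".csv"))
    write_trace_csv(tr, p, dialect)
    p
  }, character(1))
  for (nm in names(cohort$truth)) {
    p <- file.path(dir, paste0("truth_", nm, ".csv"))
    utils::write.csv(cohort$truth[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(unname(paths))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_cells <- sum(vapply(x$traces, function(tr) nrow(tr$samples), numeric(1)))
  cat(sprintf("<synthetic_cohort> %d neonates, %.0f monitored hours, %d planted episodes\n",
              length(x$traces), n_cells * 2 / 3600, nrow(x$truth$episodes)))
  invisible(x)
}

#' Pooled calibration statistics of a cohort
#'
#' Quality-filters every trace, pools the valid SpO2 and PR samples, and
#' re-derives the SpO2 alarm events under `settings` to compute the pooled
#' statistics the generator is calibrated against: the SpO2 median and tail
#' percentages (below 85%, outside 85-96%, below 80.2%), the PR mean, SD
#' and tail percentages (outside 90-200, below 90), the high-alarm share of
#' SpO2 alarm events, and the median SpO2 alarm event duration.
#'
#' @param x A `synthetic_cohort`, or a list of `ox_trace` objects.
#' @param settings [alarm_settings()] for the re-derived alarm stream.
#' @param config [segmentation_config()] for event grouping.
#' @return A list of class `calibration_summary` with elements `stats`
#'   (named numeric), `n` (named problem sizes) and `per_neonate`
#'   (sufficient statistics used for resampling standard errors).
#' @export
calibration_summary <- function(x, settings = alarm_settings(),
                                config = segmentation_config()) {
  traces <- if (inherits(x, "synthetic_cohort")) x$traces else x
  per <- lapply(traces, function(tr) {
    flt <- apply_quality_rules(tr)$trace
    spo2 <- flt$samples$spo2[valid_mask(flt, "spo2")]
    pr <- flt$samples$pr[valid_mask(flt, "pr")]
    ev <- simulate_alarm_stream(flt, settings, config)
    ev <- ev[ev$category %in% c("spo2_low", "spo2_high"), , drop = FALSE]
    list(
      spo2_counts = tabulate(spo2 + 1L, 101L),
      pr_counts = tabulate(pr + 1L, 301L),
      dur_low = ev$duration_s[ev$category == "spo2_low"],
      dur_high = ev$duration_s[ev$category == "spo2_high"]
    )
  })
  out <- summarize_calibration(per)
  out$per_neonate <- per
  class(out) <- "calibration_summary"
  out
}

# Compute the pooled statistics from per-neonate sufficient statistics
# (shared with the resampling standard-error machinery).
summarize_calibration <- function(per) {
  spo2_counts <- Reduce(`+`, lapply(per, `[[`, "spo2_counts"))
  pr_counts <- Reduce(`+`, lapply(per, `[[`, "pr_counts"))
  dur_low <- unlist(lapply(per, `[[`, "dur_low"), use.names = FALSE)
  dur_high <- unlist(lapply(per, `[[`, "dur_high"), use.names = FALSE)
  v_spo2 <- 0:100
  v_pr <- 0:300
  n_spo2 <- sum(spo2_counts)
  n_pr <- sum(pr_counts)
  hist_quantile <- function(v, cnt, p) {
    n <- sum(cnt)
    if (n == 0L) return(NA_real_)
    cum <- cumsum(cnt)
    v[which(cum >= p * n)[1]]
  }
  pct_below <- function(v, cnt, x) 100 * sum(cnt[v < x]) / sum(cnt)
  pct_above <- function(v, cnt, x) 100 * sum(cnt[v > x]) / sum(cnt)
  pr_mean <- sum(v_pr * pr_counts) / n_pr
  pr_sd <- sqrt(sum(v_pr^2 * pr_counts) / n_pr - pr_mean^2)
  n_ev <- length(dur_low) + length(dur_high)
  stats <- c(
    spo2_median_pct = hist_quantile(v_spo2, spo2_counts, 0.5),
    spo2_below_85_pct = pct_below(v_spo2, spo2_counts, 85),
    spo2_outside_85_96_pct = pct_below(v_spo2, spo2_counts, 85) +
      pct_above(v_spo2, spo2_counts, 96),
    spo2_below_80_2_pct = pct_below(v_spo2, spo2_counts, 80.2),
    pr_mean_bpm = pr_mean,
    pr_sd_bpm = pr_sd,
    pr_outside_90_200_pct = pct_below(v_pr, pr_counts, 90) +
      pct_above(v_pr, pr_counts, 200),
    pr_below_90_pct = pct_below(v_pr, pr_counts, 90),
    spo2_high_alarm_share_pct =
      if (n_ev > 0) 100 * length(dur_high) / n_ev else NA_real_,
    spo2_alarm_median_duration_s = median_na(c(dur_low, dur_high))
  )
  n <- c(
    spo2_median_pct = n_spo2, spo2_below_85_pct = n_spo2,
    spo2_outside_85_96_pct = n_spo2, spo2_below_80_2_pct = n_spo2,
    pr_mean_bpm = n_pr, pr_sd_bpm = n_pr,
    pr_outside_90_200_pct = n_pr, pr_below_90_pct = n_pr,
    spo2_high_alarm_share_pct = n_ev, spo2_alarm_median_duration_s = n_ev
  )
  list(stats = stats, n = n)
}

#' @export
print.calibration_summary <- function(x, ...) {
  cat("<calibration_summary>\n")
  for (nm in names(x$stats)) {
    cat(sprintf("  %-28s %10.4g  (n = %d)\n", nm, x$stats[[nm]],
                as.integer(x$n[[nm]])))
  }
  invisible(x)
}

#' Monte-Carlo standard errors of the calibration statistics
#'
#' Nonparametric bootstrap over neonates (the generator's unit of
#' replication): resamples neonate ids with replacement and recomputes each
#' pooled statistic from the per-neonate sufficient statistics.
#'
#' @param summary A `calibration_summary`.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return Named numeric vector of standard errors.
#' @export
calibration_bootstrap_se <- function(summary, n_boot = 200, seed = 1) {
  per <- summary$per_neonate
  k <- length(per)
  reps <- withr_seed(seed, function() {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(k, k, replace = TRUE)
      summarize_calibration(per[pick])$stats
    }, numeric(length(summary$stats)))
  })
  apply(reps, 1, stats::sd)
}
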