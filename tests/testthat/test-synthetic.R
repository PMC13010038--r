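test_that("the same spec and seed reproduce the cohort byte for byte", {
  spec <- mini_spec(n_neonates = 2, seed = 123)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
  # and a written trace file is byte-identical too
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(a$traces[[1]], p1)
  write_trace_csv(b$traces[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))

  c <- generate_cohort(mini_spec(n_neonates = 2, seed = 124))
  expect_false(identical(a$traces, c$traces))
})

test_that("generated annotations equal re-running the alarm simulator", {
  co <- generate_cohort(mini_spec(n_neonates = 2, seed = 31))
  for (tr in co$traces) {
    sim <- simulate_alarm_stream(tr, co$spec$settings,
                                 segmentation_config(co$spec$gap_s))
    truth <- co$truth$alarm_events[
      co$truth$alarm_events$neonate_id == tr$neonate_id, ]
    cols <- c("category", "start_t", "end_t", "active_cell_count",
              "duration_s", "merged_across_gap")
    got <- sim[order(sim$start_t, sim$category), cols]
    want <- truth[order(truth$start_t, truth$category), cols]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("segmenting an artifact-free cohort recovers the planted truth exactly", {
  spec <- mini_spec(n_neonates = 2, seed = 77, artifact_rate = 0,
                    desat_rate = 3, high_rate = 3, min_gap_s = 60,
                    siq_rate = 0)
  co <- generate_cohort(spec)
  for (tr in co$traces) {
    flt <- apply_quality_rules(tr)$trace
    ev <- segment_events(flt, segmentation_config(spec$gap_s))
    ev <- ev[ev$category != "system", ]
    truth <- co$truth$alarm_events[
      co$truth$alarm_events$neonate_id == tr$neonate_id, ]
    cols <- c("category", "modality", "start_t", "end_t",
              "active_cell_count", "duration_s", "merged_across_gap")
    got <- ev[order(ev$start_t, ev$category), cols]
    want <- truth[order(truth$start_t, truth$category), cols]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)

    # the annotated cells also match the independent scalar reference
    s <- tr$samples
    st <- spec$settings
    ref_low <- oracle_alarm_cells(s$t, s$spo2, st$spo2_low, "low", st$delay_s,
                                  st$averaging_s,
                                  st$spo2_low - st$rapid_desat_pct)
    act <- alarm_active_cells(tr, st)
    expect_equal(act$spo2_low, ref_low)
    expect_equal(act$spo2_high,
                 oracle_alarm_cells(s$t, s$spo2, st$spo2_high, "high",
                                    st$delay_s, st$averaging_s))
  }
  # every sufficiently deep or long planted desaturation yields at least one
  # recovered low event within its span (the 8 s averaging can delay the
  # violation by up to 3 cells, so a dip must outlast delay + entry lag, or
  # hold an averaged value in the rapid-desaturation zone)
  ep <- co$truth$episodes
  desats <- ep[ep$type == "desat" &
                 (ep$dwell_s >= 24 | (ep$value <= 75 & ep$dwell_s >= 8)), ]
  ev_all <- co$truth$alarm_events
  low <- ev_all[ev_all$category == "spo2_low", ]
  hit <- vapply(seq_len(nrow(desats)), function(i) {
    any(low$neonate_id == desats$neonate_id[i] &
          low$start_t >= desats$start_t[i] &
          low$start_t < desats$start_t[i] + desats$dwell_s[i])
  }, logical(1))
  expect_true(all(hit))
})

test_that("degenerate specs behave as documented", {
  # no desaturations and a baseline confined to 90-96: no clinical alarms
  spec <- mini_spec(n_neonates = 1, seed = 5, artifact_rate = 0,
                    desat_rate = 0, high_rate = 0, siq_rate = 0)
  spec$spo2$inrange_values <- 90:96
  spec$spo2$inrange_marginal <- rep(1 / 7, 7)
  spec$spo2$inrange_mean_len <- rep(5, 7)
  spec$pr$brady_rate_per_h <- 0
  spec$pr$brady_couple_p <- 0
  spec$pr$tachy_rate_per_h <- 0
  co <- generate_cohort(spec)
  expect_equal(nrow(co$truth$alarm_events), 0L)
  expect_true(all(co$traces[[1]]$samples$spo2 %in% 90:96))

  # infeasible episode load is rejected
  bad <- mini_spec(n_neonates = 1, seed = 5)
  bad$spo2$desat_rate_per_h <- 2000
  expect_error(generate_cohort(bad), "infeasible")

  # artifact segments longer than the shortest monitoring duration
  bad2 <- mini_spec(n_neonates = 1, seed = 5)
  bad2$artifact$mean_s <- 10 * 86400
  expect_error(generate_cohort(bad2), "infeasible")
})

test_that("raising the desaturation rate raises the sub-85 tail mass", {
  lo <- generate_cohort(mini_spec(n_neonates = 2, seed = 8, artifact_rate = 0,
                                  desat_rate = 2, median_days = 0.15))
  hi <- generate_cohort(mini_spec(n_neonates = 2, seed = 8, artifact_rate = 0,
                                  desat_rate = 10, median_days = 0.15))
  tail_mass <- function(co) {
    v <- unlist(lapply(co$traces, function(tr) tr$samples$spo2))
    mean(v[!is.na(v)] < 85)
  }
  expect_gt(tail_mass(hi), tail_mass(lo))
})

test_that("the default calibration satisfies the median-96 feasibility arithmetic", {
  # for the pooled median to sit at 96 while half the mass is outside
  # 85-96, the point mass at exactly 96 must be at least
  # 0.5 - P(above 96); the shipped in-range marginal provides it
  spec <- default_calibration()
  f_low <- 5.78 / 100
  f_high <- (50 - 5.78) / 100
  f_base <- 1 - f_low - f_high
  mass_96 <- f_base * spec$spo2$inrange_marginal[spec$spo2$inrange_values == 96]
  expect_gte(mass_96, 0.5 - f_high)
  # and P(<= 95) stays below one half so the median cannot slip downward
  expect_lt(f_low + f_base * (1 - spec$spo2$inrange_marginal[
    spec$spo2$inrange_values == 96]), 0.5)
})

test_that("quality exclusions on the default generator are near the unit's report", {
  co <- generate_cohort(mini_spec(n_neonates = 3, seed = 61,
                                  median_days = 0.3))
  reports <- lapply(co$traces, function(tr) apply_quality_rules(tr)$report)
  excl <- sum(vapply(reports, `[[`, numeric(1), "excluded_duration_h")) /
    sum(vapply(reports, `[[`, numeric(1), "total_duration_h"))
  expect_gt(excl, 0.05)
  expect_lt(excl, 0.16)
  null_fracs <- vapply(reports, `[[`, numeric(1),
                       "spo2_null_fraction_in_excluded")
  expect_true(all(null_fracs > 0.5 & null_fracs < 0.95))
})

test_that("a written cohort round-trips through the trace dialect", {
  co <- generate_cohort(mini_spec(n_neonates = 2, seed = 41))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_true(all(file.exists(paths)))
  back <- read_trace_csv(file.path(dir, "N01.csv"))
  expect_equal(back$samples, co$traces[["N01"]]$samples)
  truth <- read.csv(file.path(dir, "truth_episodes.csv"))
  expect_equal(nrow(truth), nrow(co$truth$episodes))
})
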