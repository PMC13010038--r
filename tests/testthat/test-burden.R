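test_that("alarm_density divides events by hours", {
  ev <- data.frame(duration_s = rep(10, 8))
  expect_equal(alarm_density(ev, 2), 4)
  expect_equal(alarm_density(ev[0, , drop = FALSE], 2), 0)
  expect_error(alarm_density(ev, 0), "positive")
})

test_that("duration buckets are right-closed (30 s falls in the <=30 bucket)", {
  pct <- duration_bucket_percentages(c(10, 20, 40), edges = 30)
  expect_equal(unname(pct), c(2 / 3, 1 / 3) * 100)

  all30 <- duration_bucket_percentages(rep(30, 12), edges = 30)
  expect_equal(unname(all30[1]), 100)

  one <- duration_bucket_percentages(45, edges = c(30, 60))
  expect_equal(unname(one), c(0, 100, 0))

  expect_error(duration_bucket_percentages(numeric(0), 30), "no events")
  expect_error(duration_bucket_percentages(c(1, 2), c(60, 30)), "increasing")

  # invariant under reordering
  set.seed(5)
  d <- sample(1:600, 200, replace = TRUE)
  expect_equal(duration_bucket_percentages(d),
               duration_bucket_percentages(sample(d)))
  expect_equal(sum(duration_bucket_percentages(d)), 100)
})

test_that("out_of_range_fraction uses strict inequalities over valid samples", {
  tr <- make_trace(4, spo2 = c(90, 90, 90, 90))
  expect_equal(out_of_range_fraction(tr, 85, 96, "spo2"),
               list(below = 0, above = 0))

  tr2 <- make_trace(4, spo2 = c(84, 85, 96, 97))
  expect_equal(out_of_range_fraction(tr2, 85, 96, "spo2"),
               list(below = 0.25, above = 0.25))

  expect_equal(out_of_range_fraction(tr2, 85, NULL, "spo2")$above, 0)

  # null samples are not in the denominator
  tr3 <- make_trace(4, spo2 = c(80, NA, NA, 90))
  expect_equal(out_of_range_fraction(tr3, 85, 96, "spo2")$below, 0.5)
  tr4 <- make_trace(2, spo2 = c(NA, NA))
  expect_error(out_of_range_fraction(tr4, 85, 96, "spo2"), "no valid samples")

  # monotone in the threshold
  set.seed(6)
  v <- sample(60:100, 500, replace = TRUE)
  lows <- seq(70, 95, by = 1)
  below <- vapply(lows, function(l) out_of_range_fraction(v, l, NULL)$below,
                  numeric(1))
  expect_true(all(diff(below) >= 0))
})

test_that("cohort summaries aggregate per-neonate values, never pooled cells", {
  ev <- rbind(
    data.frame(neonate_id = "A", category = "spo2_low", modality = "audio_visual",
               start_t = c(0, 100), end_t = c(10, 110), active_cell_count = 5L,
               duration_s = 10, merged_across_gap = FALSE),
    data.frame(neonate_id = "B", category = "spo2_high", modality = "visual",
               start_t = 0, end_t = 20, active_cell_count = 10L,
               duration_s = 20, merged_across_gap = FALSE)
  )
  hours <- c(A = 1, B = 0.5)
  per <- per_neonate_burden(ev, hours)
  expect_equal(per$n_alarms, c(2L, 1L))
  expect_equal(per$alarms_per_hour, c(2, 2))
  expect_equal(per$audible_per_hour, c(2, 0))
  expect_equal(per$visual_per_hour, c(2, 2))

  cs <- cohort_summary(per, ev)
  expect_equal(cs$cohort$total_alarms, 3L)
  expect_equal(sum(per$n_alarms), cs$cohort$total_alarms)
  expect_equal(unname(cs$cohort$density_per_hour["median"]), 2)

  one <- cohort_summary(per[1, , drop = FALSE])
  expect_equal(unname(one$cohort$density_per_hour["iqr"]), 0)
})

test_that("cohort medians and IQR match the quantile oracle", {
  per <- data.frame(
    neonate_id = c("A", "B", "C"), hours = 1, n_alarms = c(2L, 4L, 9L),
    alarms_per_hour = c(2, 4, 9), audible_per_hour = c(1, 2, 3),
    visual_per_hour = c(2, 4, 9), median_duration_s = c(10, 12, 30),
    iqr_duration_s = 0, n_spo2_low = 0L, n_spo2_high = 0L, n_pr_low = 0L,
    n_pr_high = 0L, n_system = 0L
  )
  cs <- cohort_summary(per)
  expect_equal(unname(cs$cohort$density_per_hour["median"]), 4)
  expect_equal(unname(cs$cohort$density_per_hour["iqr"]),
               unname(diff(quantile(c(2, 4, 9), c(0.25, 0.75)))))

  set.seed(7)
  per2 <- per[rep(1, 40), ]
  per2$alarms_per_hour <- rexp(40, 0.1)
  per2$neonate_id <- sprintf("N%02d", 1:40)
  cs2 <- cohort_summary(per2)
  expect_equal(unname(cs2$cohort$density_per_hour["median"]),
               unname(quantile(per2$alarms_per_hour, 0.5, type = 7)))
})

test_that("hourly and daily maxima use clock-aligned windows from first sample", {
  ev <- data.frame(
    neonate_id = "A", category = "spo2_low", modality = "audio_visual",
    start_t = c(0, 1800, 3599, 3600, 7300), end_t = c(10, 1810, 3609, 3610, 7310),
    active_cell_count = 5L, duration_s = 10, merged_across_gap = FALSE
  )
  per <- per_neonate_burden(ev, c(A = 3))
  cs <- cohort_summary(per, ev)
  expect_equal(cs$cohort$max_hourly_count, 3L)
  expect_equal(cs$cohort$max_daily_count, 5L)
})
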