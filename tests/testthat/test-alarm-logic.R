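test_that("moving_average matches hand-computed trailing means", {
  expect_equal(moving_average(c(100, 100, 90, 90), 8),
               c(100, 100, 290 / 3, 95))
  expect_equal(moving_average(rep(95, 10), 8), rep(95, 10))
  x <- c(93, 91, NA, 96)
  expect_identical(moving_average(x, 2), x)
  # nulls are excluded from the window; an all-null window is null
  expect_equal(moving_average(c(NA, NA, 90, NA), 4), c(NA, NA, 90, 90))
  expect_equal(moving_average(c(NA, NA), 4), c(NA_real_, NA_real_))
  expect_error(moving_average(1:3, 5), "multiple")
})

test_that("averaged values stay within the window's range", {
  set.seed(30)
  for (i in 1:20) {
    x <- sample(c(70:100, NA), 50, replace = TRUE)
    for (w in c(4, 8, 16)) {
      m <- moving_average(x, w)
      k <- w / 2
      for (j in seq_along(x)) {
        win <- x[max(1, j - k + 1):j]
        win <- win[!is.na(win)]
        if (length(win) == 0) expect_true(is.na(m[j])) else {
          expect_gte(m[j], min(win))
          expect_lte(m[j], max(win))
        }
      }
    }
  }
})

test_that("an in-range trace raises no alarms", {
  tr <- make_trace(100, spo2 = rep(90, 100), pr = rep(150, 100))
  expect_equal(nrow(simulate_alarm_stream(tr)), 0L)
})

test_that("the 15 s delay asserts at the 8th violating cell", {
  tr <- make_trace(40, spo2 = rep(80, 40), pr = rep(150, 40))
  act <- alarm_active_cells(tr)
  expect_equal(act$spo2_low, 8:40)
  ev <- simulate_alarm_stream(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_t, tr$samples$t[8])
  expect_equal(ev$duration_s, 33 * 2)
})

test_that("a rapid desaturation bypasses the delay", {
  tr <- make_trace(40, spo2 = rep(70, 40), pr = rep(150, 40))
  act <- alarm_active_cells(tr)
  # averaged SpO2 is 70 from the first cell (partial window), at or below
  # 85 - 10, so the low alarm asserts immediately
  expect_equal(act$spo2_low, 1:40)

  # a drop from baseline: the averaging window delays the deep condition
  tr2 <- make_trace(40, spo2 = c(rep(92, 10), rep(70, 30)), pr = rep(150, 40))
  act2 <- alarm_active_cells(tr2)
  ref <- oracle_alarm_cells(tr2$samples$t, tr2$samples$spo2, 85, "low", 15, 8,
                            rapid_desat_threshold = 75)
  expect_equal(act2$spo2_low, ref)
  expect_lt(min(act2$spo2_low), 10 + 8)  # earlier than the plain delay
})

test_that("delay 0 with 2 s averaging reproduces raw threshold crossings", {
  set.seed(31)
  st <- alarm_settings(delay_s = 0, averaging_s = 2)
  for (i in 1:30) {
    tr <- random_vitals_trace(150)
    act <- alarm_active_cells(tr, st)
    s <- tr$samples
    expect_equal(act$spo2_low, which(!is.na(s$spo2) & s$spo2 < 85))
    expect_equal(act$spo2_high, which(!is.na(s$spo2) & s$spo2 > 96))
    expect_equal(act$pr_low, which(!is.na(s$pr) & s$pr < 90))
    expect_equal(act$pr_high, which(!is.na(s$pr) & s$pr > 200))
  }
})

test_that("the vectorized state machine matches the scalar reference", {
  set.seed(32)
  for (i in 1:40) {
    tr <- random_vitals_trace(150)
    st <- alarm_settings(
      delay_s = sample(c(0, 6, 10, 15, 30), 1),
      averaging_s = sample(c(2, 4, 8, 16), 1),
      rapid_desat_pct = sample(c(0, 10, 15), 1)
    )
    act <- alarm_active_cells(tr, st)
    s <- tr$samples
    expect_equal(act$spo2_low,
                 oracle_alarm_cells(s$t, s$spo2, st$spo2_low, "low",
                                    st$delay_s, st$averaging_s,
                                    st$spo2_low - st$rapid_desat_pct),
                 info = paste("iter", i))
    expect_equal(act$spo2_high,
                 oracle_alarm_cells(s$t, s$spo2, st$spo2_high, "high",
                                    st$delay_s, st$averaging_s))
    expect_equal(act$pr_low,
                 oracle_alarm_cells(s$t, s$pr, st$pr_low, "low",
                                    st$delay_s, st$averaging_s))
    expect_equal(act$pr_high,
                 oracle_alarm_cells(s$t, s$pr, st$pr_high, "high",
                                    st$delay_s, st$averaging_s))
  }
})

test_that("activation counts are non-increasing in the delay", {
  set.seed(33)
  delays <- c(0, 6, 10, 15, 30, 60)
  for (i in 1:25) {
    tr <- random_vitals_trace(150)
    counts <- vapply(delays, function(d) {
      sum(alarm_activation_counts(tr, alarm_settings(delay_s = d)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0), info = paste("iter", i))
  }
})

test_that("disabling the upper threshold yields zero high alarms", {
  set.seed(34)
  st <- alarm_settings(spo2_high = NULL, pr_high = NULL, delay_s = 0,
                       averaging_s = 2)
  for (i in 1:10) {
    tr <- random_vitals_trace(100)
    ev <- simulate_alarm_stream(tr, st)
    expect_equal(sum(ev$category %in% c("spo2_high", "pr_high")), 0L)
  }
})

test_that("what_if_sweep is consistent with simulate_alarm_stream and deterministic", {
  set.seed(35)
  traces <- replicate(3, random_vitals_trace(120), simplify = FALSE)
  grid <- settings_grid(delay_s = c(0, 15), spo2_high = list(96, NULL))
  sw <- what_if_sweep(traces, grid)
  expect_equal(nrow(sw), 4L)
  defaults_row <- sw[sw$delay_s == 15 & !is.na(sw$spo2_high), ]
  ev <- do.call(rbind, lapply(traces, simulate_alarm_stream))
  expect_equal(defaults_row$n_total, nrow(ev))
  expect_equal(defaults_row$n_spo2_low, sum(ev$category == "spo2_low"))
  expect_true(all(sw$n_spo2_high[is.na(sw$spo2_high)] == 0))
  expect_identical(sw, what_if_sweep(traces, grid))

  # excluded cells are unavailable to the simulator
  tr <- make_trace(60, spo2 = rep(80, 60))
  tr$samples$events[1:60] <- "Sensor Off"
  flt <- apply_quality_rules(tr)$trace
  expect_equal(nrow(simulate_alarm_stream(flt)), 0L)
})
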