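test_that("a contiguous alarm run forms one event with duration 2 s per cell", {
  tr <- annotate_cells(make_trace(30), list(spo2_low = 6:15))
  ev <- segment_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$active_cell_count, 10L)
  expect_equal(ev$duration_s, 20)
  expect_equal(ev$category, "spo2_low")
  expect_false(ev$merged_across_gap)
})

test_that("exactly 30 s of silence merges, more than 30 s splits", {
  # run of 5, then silence, then run of 5; cells are 2 s wide, so silence
  # between cell k (ending at t+2) and cell m (starting at t') is t'-t-2
  tr30 <- annotate_cells(make_trace(60), list(spo2_low = c(1:5, 21:25)))
  # last cell of run 1 at t=8 ends at 10; run 2 starts at t=40: silence 30 s
  ev30 <- segment_events(tr30)
  expect_equal(nrow(ev30), 1L)
  expect_equal(ev30$active_cell_count, 10L)
  expect_equal(ev30$duration_s, 20)
  expect_true(ev30$merged_across_gap)

  tr32 <- annotate_cells(make_trace(60), list(spo2_low = c(1:5, 22:26)))
  # silence 32 s
  ev32 <- segment_events(tr32)
  expect_equal(nrow(ev32), 2L)
  expect_equal(ev32$active_cell_count, c(5L, 5L))
})

test_that("a category change always starts a new event", {
  tr <- annotate_cells(make_trace(30),
                       list(spo2_low = 1:5, spo2_high = 6:10))
  ev <- segment_events(tr)
  expect_equal(nrow(ev), 2L)
  expect_setequal(ev$category, c("spo2_low", "spo2_high"))
  expect_equal(ev$active_cell_count, c(5L, 5L))
})

test_that("an unannotated trace yields no events", {
  expect_equal(nrow(segment_events(make_trace(40))), 0L)
})

test_that("segment_events matches the brute-force oracle on random traces", {
  set.seed(20)
  cfg <- segmentation_config()
  for (i in 1:200) {
    tr <- random_annotated_trace(120)
    ev <- segment_events(tr)
    flags <- cell_label_flags(tr$samples$events)
    for (cat in c("spo2_low", "spo2_high", "pr_low", "pr_high")) {
      got <- ev[ev$category == cat,
                c("start_t", "end_t", "active_cell_count", "duration_s",
                  "merged_across_gap")]
      rownames(got) <- NULL
      want <- oracle_merge_cells(tr$samples$t[flags[[cat]]$flag], cfg$gap_s)
      expect_equal(got, want, info = sprintf("iter %d cat %s", i, cat))
    }
  }
})

test_that("cell conservation holds per category", {
  set.seed(21)
  for (i in 1:25) {
    tr <- random_annotated_trace(150)
    ev <- segment_events(tr)
    flags <- cell_label_flags(tr$samples$events)
    for (cat in c("spo2_low", "spo2_high", "pr_low", "pr_high")) {
      expect_equal(sum(ev$active_cell_count[ev$category == cat]),
                   sum(flags[[cat]]$flag))
    }
  }
})

test_that("increasing gap_s never increases the event count; gap 0 gives maximal runs", {
  set.seed(22)
  for (i in 1:25) {
    tr <- random_annotated_trace(150)
    counts <- vapply(c(0, 2, 10, 30, 60, 1e6), function(g) {
      nrow(segment_events(tr, segmentation_config(gap_s = g)))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    # gap 0: every within-event step is exactly one cell
    ev0 <- segment_events(tr, segmentation_config(gap_s = 0))
    expect_true(all(!ev0$merged_across_gap))
    expect_equal(ev0$duration_s, ev0$end_t - ev0$start_t)
  }
})

test_that("event modality aggregates audible/visual cells", {
  tr <- make_trace(20)
  tr$samples$events[3:5] <- "SpO2 Low Alarm (Silenced)"
  ev <- segment_events(tr)
  expect_equal(ev$modality, "visual")

  tr$samples$events[6] <- "SpO2 Low Alarm"
  ev2 <- segment_events(tr)
  expect_equal(ev2$modality, "audio_visual")
})

test_that("classify_event resolves category and modality", {
  labs <- parse_event_labels("SpO2 Low Alarm (Silenced)")
  out <- classify_event(labs, list(audible = FALSE, visual = TRUE))
  expect_equal(out$category, "spo2_low")
  expect_equal(out$modality, "visual")

  out2 <- classify_event(parse_event_labels("PR High Alarm"),
                         list(audible = TRUE, visual = FALSE))
  expect_equal(out2$category, "pr_high")
  expect_equal(out2$modality, "audible")

  out3 <- classify_event(parse_event_labels("SpO2 Low Alarm"),
                         list(audible = c(TRUE, FALSE), visual = c(FALSE, TRUE)))
  expect_equal(out3$modality, "audio_visual")

  mixed <- rbind(parse_event_labels("SpO2 Low Alarm"),
                 parse_event_labels("PR Low Alarm"))
  expect_error(classify_event(mixed, list(audible = TRUE, visual = TRUE)),
               "conflicting")
})
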