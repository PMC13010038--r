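test_that("write/read round-trips a trace exactly", {
  set.seed(4)
  tr <- random_annotated_trace(80)
  tr$samples$spo2[5] <- NA
  tr$samples$events[5] <- paste0(tr$samples$events[5],
                                 ifelse(nzchar(tr$samples$events[5]), ";", ""),
                                 "Invalid functional SpO2")
  tr$samples$pi <- round(runif(nrow(tr$samples), 0.3, 5), 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_identical(back$neonate_id, tr$neonate_id)
  expect_identical(back$device_id, tr$device_id)
  expect_equal(back$samples, tr$samples)
  # write(read(.)) is stable byte for byte
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invalid-entry tokens become nulls with the label retained", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "# neonate_id: N77",
    "# device_id: OXI-03",
    "time_s,spo2,pr,pi,siq,events",
    "0,95,150,1.2,ok,",
    "2,Invalid functional SpO2,150,1.2,ok,",
    "4,93,Invalid PR,1.1,low,",
    "6,,,,ok,"
  ), path)
  tr <- read_trace_csv(path)
  expect_identical(tr$neonate_id, "N77")
  expect_equal(tr$samples$spo2, c(95, NA, 93, NA))
  expect_equal(tr$samples$pr, c(150, 150, NA, NA))
  labs2 <- parse_event_labels(tr$samples$events[2])
  expect_true("Invalid functional SpO2" %in% labs2$raw)
  labs3 <- parse_event_labels(tr$samples$events[3])
  expect_true("Invalid PR" %in% labs3$raw)
  # plain missing cells carry no invalid marker
  expect_identical(tr$samples$events[4], "")

  # null-token bijection
  s <- tr$samples
  expect_equal(sum(has_token(s$events, "Invalid functional SpO2")),
               sum(is.na(s$spo2) & nzchar(s$events)))
})

test_that("reader errors cite the offending row or column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time_s,spo2,pr,pi,siq,events",
    "0,95,150,1.2,ok,",
    "2,96,150,1.2,ok,",
    "1,94,150,1.2,ok,"
  ), path)
  expect_error(read_trace_csv(path), "row 3")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time_s,spo2,pr,pi,events",
    "0,95,150,1.2,"
  ), path2)
  expect_error(read_trace_csv(path2), "siq")

  expect_error(read_trace_csv(file.path(tempdir(), "absent-trace.csv")),
               "not found")
})

test_that("trace invariants are enforced", {
  expect_error(make_trace(4, spo2 = c(95, 101, 96, 96)), "out of range")
  expect_error(make_trace(4, t = c(0, 2, 3, 6)), "multiple")
  s <- make_samples(3)
  s$events[2] <- "Invalid functional SpO2"  # but spo2 not null
  expect_error(ox_trace(s), "invalid-SpO2")
})

test_that("ISO-8601 timestamps normalize to seconds from trace start", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time_s,spo2,pr,pi,siq,events",
    "2021-10-04T10:00:00,95,150,1.2,ok,",
    "2021-10-04T10:00:02,96,151,1.2,ok,",
    "2021-10-04T10:00:06,94,150,1.1,ok,"
  ), path)
  tr <- read_trace_csv(path, trace_dialect(time = "iso8601"))
  expect_equal(tr$samples$t, c(0, 2, 6))
})
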