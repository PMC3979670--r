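eth <- default_ethogram()

test_that("contiguous same-behavior records merge into one bout", {
  log <- event_log(make_records("fly1", "W", 0, 10, "fly1", "W", 10, 20),
                   ethogram = eth)
  expect_equal(nrow(log$records), 1)
  expect_equal(log$records$onset_s, 0)
  expect_equal(log$records$offset_s, 20)
  expect_equal(bout_durations(log, "W"), 20)
})

test_that("overlapping events for one subject are rejected with timestamps", {
  expect_error(
    event_log(make_records("fly1", "W", 0, 10, "fly1", "Sta", 5, 15),
              ethogram = eth),
    "overlap.*fly1.*5")
})

test_that("raw low-intensity codes are stored as Lo at read", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- make_records("fly1", "fencing", 1, 1.4, "fly1", "W", 2, 8)
  write.csv(df, f, row.names = FALSE)
  log <- read_event_log(f, eth)
  expect_setequal(unique(log$records$behavior), c("Lo", "W"))
})

test_that("unknown behavior codes are a validation error", {
  expect_error(event_log(make_records("fly1", "Zz", 0, 1), ethogram = eth),
               "unknown behavior.*Zz")
})

test_that("event-log CSV round-trips, including gzip", {
  cfg <- default_parameters(3)
  log <- generate_session(cfg, seed = 5)
  for (ext in c(".csv", ".csv.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_event_log(log, f)
    back <- read_event_log(f, eth)
    expect_equal(back$records$behavior, log$records$behavior)
    expect_equal(back$records$onset_s, log$records$onset_s, tolerance = 1e-12)
  }
})

test_that("time budget pools subjects and handles full occupancy", {
  one <- event_log(make_records("fly1", "Sta", 0, 3600), ethogram = eth)
  expect_equal(time_budget(one)$proportions[["Sta"]], 1.0)
  two <- event_log(make_records("fly1", "W", 0, 1800, "fly1", "G", 1800, 3600,
                                "fly2", "G", 0, 1800, "fly2", "W", 1800, 3600),
                   ethogram = eth)
  tb <- time_budget(two)
  expect_equal(tb$proportions[["W"]], 0.5)
  expect_equal(tb$proportions[["G"]], 0.5)
  expect_error(time_budget(list()), "empty")
})

test_that("time budget is invariant to subject relabeling and log order", {
  cfg <- default_parameters(1)
  logs <- generate_cohort(cfg, 3, seed = 21)
  tb1 <- time_budget(logs, c("W", "Sta", "G", "U"))
  relab <- lapply(rev(logs), function(l) {
    r <- l$records
    r$subject_id <- ifelse(r$subject_id == "fly1", "flyB", "flyA")
    event_log(r, l$session_duration_s)
  })
  tb2 <- time_budget(relab, c("W", "Sta", "G", "U"))
  expect_equal(tb1$proportions, tb2$proportions, tolerance = 1e-12)
})

test_that("bout durations list bouts in encounter order", {
  log <- event_log(make_records("fly1", "Wr", 12, 14.5), ethogram = eth)
  expect_equal(bout_durations(log, "Wr"), 2.5)
  log2 <- event_log(make_records("fly1", "H", 0, 2, "fly1", "H", 10, 18.2),
                    ethogram = eth)
  expect_equal(bout_durations(log2, "H"), c(2.0, 8.2))
  expect_equal(bout_durations(log2, "Wr"), numeric(0))
})

test_that("occurrence rates are per individual per hour and scale linearly", {
  half <- event_log(make_records("fly1", "L", (0:9) * 100, (0:9) * 100 + 0.4),
                    session_duration_s = 1800, ethogram = eth)
  r <- occurrence_rate(list(half), "L")
  expect_equal(r$rates, 20)
  expect_equal(occurrence_rate(list(half), "B")$rates, 0)
  # duplicating a log duplicates individuals but keeps every rate
  r2 <- occurrence_rate(list(half, half), "L")
  expect_equal(r2$rates, c(20, 20))
  expect_equal(r2$mean, 20)
})

test_that("interval counting trims ends and assigns onsets half-open", {
  log <- event_log(make_records("fly1", "H", 299, 300.5,
                                "fly2", "L", 300, 300.2,
                                "fly1", "H", 900, 905,
                                "fly1", "L", 3299.9, 3300.5),
                   ethogram = eth)
  ic <- interval_counts(log)
  expect_length(ic, 5)
  # onset 299 trimmed; onset 300.0 in interval 1; 3299.9 in interval 5
  expect_equal(ic, c(1, 1, 0, 0, 1))
  short <- event_log(make_records("fly1", "H", 0, 1),
                     session_duration_s = 1000, ethogram = eth)
  expect_error(interval_counts(short), "too short")
})

test_that("single-male reads use the 50-min central window", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- make_records("fly1", "Sta", 0, 400, "fly1", "G", 400, 3300,
                     "fly1", "W", 3300, 3600)
  write.csv(df, f, row.names = FALSE)
  log <- read_event_log(f, eth, single_male = TRUE)
  expect_equal(log$session_duration_s, 3000)
  expect_equal(max(log$records$offset_s), 3000)
  # standing clipped to [300, 400] -> 100 s of 3000
  expect_equal(time_budget(log)$proportions[["Sta"]], 100 / 3000)
})

test_that("state durations never exceed the session duration", {
  for (age in c(1, 6)) {
    log <- generate_session(default_parameters(age), seed = age)
    per_subj <- tapply(log$records$offset_s - log$records$onset_s,
                       log$records$subject_id, sum)
    expect_true(all(per_subj <= log$session_duration_s + 1e-9))
  }
})
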