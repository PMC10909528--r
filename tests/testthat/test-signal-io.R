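test_that("plain x,y,z files ingest with a rate hint and preserve rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,z", sprintf("%.4f,%.4f,%.4f", runif(50), runif(50),
                                runif(50))), path)
  rec <- read_accel(path, sample_rate_hint = 25)
  expect_s3_class(rec, "accel_recording")
  expect_equal(rec$sample_rate_hz, 25)
  expect_equal(nrow(rec$data), 50)
  expect_error(read_accel(path), "sample_rate_hint")
})

test_that("a uniform timestamp column fixes the rate", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, by = 0.01, length.out = 200)
  writeLines(c("time,x,y,z", sprintf("%.5f,0,0,1", t)), path)
  rec <- read_accel(path)
  expect_equal(rec$sample_rate_hz, 100, tolerance = 1e-9)
  expect_equal(rec$start_time, 0)
})

test_that("decreasing timestamps are rejected naming the row", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, by = 0.04, length.out = 30)
  t[12] <- t[10]   # goes backwards at row 12
  writeLines(c("time,x,y,z", sprintf("%.5f,0,0,1", t)), path)
  expect_error(read_accel(path), "row 12")
})

test_that("jittery timestamps beyond 1% are a rate error", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- seq(0, by = 0.04, length.out = 50)
  t[25] <- t[25] + 0.01
  writeLines(c("time,x,y,z", sprintf("%.5f,0,0,1", t)), path)
  expect_error(read_accel(path), "jitter")
})

test_that("missing axis columns are a format error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "0,0", "0,0"), path)
  expect_error(read_accel(path, 25), "x, y, z")
})

test_that("accelerometer write/read round-trips values and metadata", {
  set.seed(7)
  rec <- accel_recording(matrix(runif(90, -2, 2), ncol = 3), 25,
                         start_time = 12.5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_accel(rec, path)
  back <- read_accel(path)
  expect_equal(back$sample_rate_hz, rec$sample_rate_hz)
  expect_equal(back$start_time, rec$start_time, tolerance = 1e-6)
  expect_equal(back$data, rec$data, tolerance = 1e-6)
})

test_that("hypnograms parse, validate stages and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("stage", "W", "N2", "N2", "R"), path)
  h <- read_hypnogram(path)
  expect_equal(h$epoch_length_s, 30)
  expect_equal(binarize_hypnogram(h)$labels,
               c("wake", "sleep", "sleep", "sleep"))
  write_hypnogram(h, path)
  expect_equal(read_hypnogram(path)$stages, h$stages)

  writeLines(c("stage"), path)
  expect_error(read_hypnogram(path), "non-empty")
  writeLines(c("stage", "W", "S4"), path)
  expect_error(read_hypnogram(path), "S4")
  h2 <- read_hypnogram(path, stage_map = c(S4 = "N3"))
  expect_equal(h2$stages, c("W", "N3"))
})

test_that("binarize maps W to wake, all sleep stages to sleep, and is
           the identity on binary input", {
  expect_equal(binarize_hypnogram(hypnogram(rep("W", 4)))$labels,
               rep("wake", 4))
  expect_equal(binarize_hypnogram(hypnogram(c("W", "N1", "W", "N3")))$labels,
               c("wake", "sleep", "wake", "sleep"))
  expect_equal(binarize_hypnogram(hypnogram(c("wake", "sleep")))$labels,
               c("wake", "sleep"))
  # total on the stage alphabet
  for (st in c("W", "N1", "N2", "N3", "R"))
    expect_true(binarize_hypnogram(hypnogram(st))$labels %in%
                  c("wake", "sleep"))
})

test_that("resampling preserves constants, duration and sine amplitude", {
  rec <- still_recording(1, rate_hz = 25)
  out <- resample_accel(rec, 30)
  expect_equal(out$sample_rate_hz, 30)
  expect_equal(nrow(out$data), 1800, tolerance = 1)
  expect_equal(max(abs(out$data[, 3] - 1)), 0, tolerance = 1e-9)
  expect_lt(abs(duration(out) - duration(rec)), 1 / 25)

  # pure 1 Hz sine at 100 Hz -> 30 Hz matches the analytic sine
  t100 <- seq(0, 60 - 1e-9, by = 1 / 100)
  rec2 <- accel_recording(cbind(x = sin(2 * pi * t100), y = 0, z = 1), 100)
  out2 <- resample_accel(rec2, 30)
  t30 <- (seq_len(nrow(out2$data)) - 1) / 30
  mid <- t30 > 5 & t30 < 55
  expect_lt(max(abs(out2$data[mid, 1] - sin(2 * pi * t30[mid]))), 0.01)

  # identity at equal rates
  expect_identical(resample_accel(rec, 25)$data, rec$data)
  expect_error(resample_accel(accel_recording(matrix(0, 1, 3), 25), 30),
               "< 2 samples")
})

test_that("apply_offset shifts only the start time and inverts", {
  rec <- still_recording(1)
  expect_identical(apply_offset(rec, 0), rec)
  expect_equal(apply_offset(apply_offset(rec, 10), -10)$start_time,
               rec$start_time)
  shifted <- apply_offset(rec, 2.5)
  expect_equal(shifted$start_time, rec$start_time + 2.5)
  expect_identical(shifted$data, rec$data)
})

test_that("interval sets enforce ordering and survive a round-trip", {
  expect_error(interval_set(10, 5), "end > start")
  expect_error(interval_set(c(0, 5), c(6, 10)), "overlap")
  iv <- interval_set(c(0, 100), c(50, 900))
  path <- withr::local_tempfile(fileext = ".csv")
  write_intervals(iv, path)
  expect_equal(read_intervals(path)$end_s, c(50, 900))
  expect_equal(nrow(read_intervals({
    p <- withr::local_tempfile(fileext = ".csv")
    writeLines("start_s,end_s", p); p
  })), 0)
})

test_that("state series round-trip through CSV", {
  s <- runs_ss(w = 20, s = 40, w = 10, step_s = 1, start_time = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_states(s, path)
  back <- read_states(path)
  expect_equal(back$labels, s$labels)
  expect_equal(back$step_s, 1)
  expect_equal(back$start_time, 5)
})
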