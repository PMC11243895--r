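test_that("ECG write/read round-trips samples and metadata", {
  rr <- rr_series(rep(800, 9))
  ecg <- generate_ecg(rr, fs = 500, subject_id = "S01", sex = "male")
  path <- withr::local_tempfile(fileext = ".txt")
  write_ecg(ecg, path)
  back <- read_ecg(path)
  expect_equal(back$samples, ecg$samples, tolerance = 1e-8)
  expect_equal(back$fs, 500)
  expect_equal(back$subject_id, "S01")
})

test_that("ECG reader rejects missing, empty and non-numeric files", {
  expect_error(read_ecg("no/such/file.txt"), "not found")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_ecg(empty, fs = 1000), "empty")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0.1", "0.2", "oops", "0.3"), bad)
  expect_error(read_ecg(bad, fs = 1000), "row 3")
})

test_that("a 60000-sample file at 1 kHz reads as a 60 s record", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(format(sin(seq_len(60000) / 100)), path)
  rec <- read_ecg(path, fs = 1000)
  expect_equal(length(rec$samples) / rec$fs, 60)
})

test_that("R-peak detection recovers clean synthetic beats exactly", {
  p <- default_state_params("alert", "any")
  rr <- generate_rr_series(30, p, seed = 12)
  ecg <- generate_ecg(rr, fs = 1000)
  pk <- detect_r_peaks(ecg)
  truth <- ecg$beat_times
  found <- pk$peak_indices / pk$fs
  expect_equal(length(found), length(truth))  # recall and precision 1
  expect_lt(max(abs(found - truth)) * 1000, 5)
})

test_that("detection survives 20 dB additive noise within 10 ms", {
  p <- default_state_params("alert", "any")
  rr <- generate_rr_series(30, p, seed = 13)
  ecg <- generate_ecg(rr, fs = 1000)
  snr <- 20
  sigma <- sqrt(mean(ecg$samples^2) / 10^(snr / 10))
  set.seed(14)
  noisy <- ecg_record(ecg$samples + rnorm(length(ecg$samples), 0, sigma),
                      ecg$fs, beat_times = ecg$beat_times)
  pk <- detect_r_peaks(noisy)
  found <- pk$peak_indices / pk$fs
  # every true beat matched within 10 ms
  err <- vapply(ecg$beat_times,
                function(bt) min(abs(found - bt)) * 1000, numeric(1))
  expect_gte(mean(err <= 10), 0.99)
  expect_equal(length(found), length(ecg$beat_times))
})

test_that("detection is invariant to offset and positive rescaling", {
  rr <- generate_rr_series(20, default_state_params("alert", "any"), seed = 2)
  ecg <- generate_ecg(rr, fs = 1000)
  pk0 <- detect_r_peaks(ecg)
  pk1 <- detect_r_peaks(ecg_record(3.7 * ecg$samples + 0.9, ecg$fs))
  expect_identical(pk0$peak_indices, pk1$peak_indices)
})

test_that("flat or too-short records are handled as contracted", {
  expect_error(detect_r_peaks(ecg_record(rep(0, 500), 1000)), "2 s")
  expect_warning(pk <- detect_r_peaks(ecg_record(rep(1, 3000), 1000)),
                 "flat|no R peaks")
  expect_length(pk$peak_indices, 0)
})

test_that("RR construction from peaks follows the sampling arithmetic", {
  pk <- structure(list(peak_indices = c(0L, 800L, 1600L), fs = 1000),
                  class = "rpeak_series")
  rr <- rr_from_peaks(pk)
  expect_equal(rr$intervals, c(800, 800))
  expect_error(rr_from_peaks(structure(list(peak_indices = 5L, fs = 1000),
                                       class = "rpeak_series")), "2 R peaks")
  # n peaks -> n - 1 intervals; interval sum telescopes to the index span
  set.seed(8)
  idx <- sort(sample.int(200000, 151))
  pk <- structure(list(peak_indices = idx, fs = 1000), class = "rpeak_series")
  rr <- rr_from_peaks(pk)
  expect_length(rr$intervals, 150)
  expect_equal(sum(rr$intervals), (idx[151] - idx[1]) / 1000 * 1000)
})

test_that("ECG round trip reproduces the generator RR within 5 ms", {
  p <- default_state_params("fatigued", "female")
  rr <- generate_rr_series(60, p, seed = 31)
  ecg <- generate_ecg(rr, fs = 1000)
  rr2 <- rr_from_peaks(detect_r_peaks(ecg))
  expect_length(rr2$intervals, length(rr$intervals))
  expect_lt(max(abs(rr2$intervals - rr$intervals)), 5)
})

test_that("artifact correction removes an inserted spike and nothing else", {
  rr <- rr_series(rep(800, 100))
  out <- correct_artifacts(rr, 0.3)
  expect_equal(attr(out, "n_corrected"), 0L)
  expect_equal(out$intervals, rr$intervals)

  iv <- rep(800, 100); iv[50] <- 1600
  fixed <- correct_artifacts(rr_series(iv), 0.3)
  expect_equal(attr(fixed, "n_corrected"), 1L)
  expect_true(all(abs(fixed$intervals - 800) < 1))

  # rel_threshold = 1 never corrects (deviation can't exceed the median)
  none <- correct_artifacts(rr_series(iv), 1)
  expect_equal(attr(none, "n_corrected"), 0L)
})

test_that("RR text round trip preserves the series", {
  rr <- generate_rr_series(90, default_state_params("alert", "any"), seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rr(rr, path)
  back <- read_rr(path)
  expect_equal(back$intervals, rr$intervals, tolerance = 1e-6)
  expect_equal(back$timestamps, rr$timestamps, tolerance = 1e-6)
})
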