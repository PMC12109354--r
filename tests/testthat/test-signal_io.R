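test_that("signal_trace enforces its invariants", {
  expect_error(signal_trace(1, 2000, "LFP"), "at least 2 samples")
  expect_error(signal_trace(c(1, 2), 0, "LFP"), "positive")
  expect_error(signal_trace(c(1, NA), 2000, "LFP"), "missing")
  expect_error(signal_trace(c(1, 2), 2000, "ECG"))
  tr <- signal_trace(c(1, 2, 3), 1000, "EMG", label = "s1")
  expect_s3_class(tr, "signal_trace")
  expect_length(tr, 3)
})

test_that("trial_set validates shape, rate and modality consistency", {
  m <- matrix(rnorm(40), nrow = 10)
  ts <- trial_set(m, rate = 10, modality = "LFP")
  expect_equal(n_trials(ts), 4)
  expect_equal(ts$epoch_seconds, 1)
  expect_error(trial_set(list()), "at least one")
  a <- signal_trace(rnorm(10), 10, "LFP")
  b <- signal_trace(rnorm(12), 10, "LFP")
  expect_error(trial_set(list(a, b)), "identical length")
  c_ <- signal_trace(rnorm(10), 20, "LFP")
  expect_error(trial_set(list(a, c_)), "sampling rate")
  d <- signal_trace(rnorm(10), 10, "EMG")
  expect_error(trial_set(list(a, d)), "modality")
  expect_error(trial_set(m, epoch_seconds = 2, rate = 10, modality = "LFP"),
               "does not match")
})

test_that("trial files round-trip through text at full precision", {
  set.seed(11)
  for (n_col in c(1, 30)) {
    ts <- trial_set(matrix(rnorm(50 * n_col), nrow = 50), rate = 50,
                    modality = "LFP")
    path <- withr::local_tempfile(fileext = ".csv")
    write_trials(ts, path)
    back <- read_trials(path, 50, "LFP")
    expect_equal(n_trials(back), n_col)
    expect_equal(back$data, ts$data, tolerance = 1e-12)
    # text representation carries >= 12 significant digits
    expect_lt(max(abs(back$data - ts$data)), 1e-12 * max(abs(ts$data)))
  }
})

test_that("a study-sized trial file reads with the expected geometry", {
  ts <- trial_set(matrix(0, nrow = 8000, ncol = 30) + rnorm(8000),
                  rate = 2000, modality = "LFP")
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(ts, path)
  back <- read_trials(path, 2000, "LFP")
  expect_equal(n_trials(back), 30)
  expect_equal(back$epoch_seconds, 4.0)
})

test_that("minimal 2-sample single-trial files are accepted", {
  path <- withr::local_tempfile()
  writeLines(c("1.5", "-2.5"), path)
  ts <- read_trials(path, 100, "EMG")
  expect_equal(n_trials(ts), 1)
  expect_equal(as.numeric(ts$data), c(1.5, -2.5))
})

test_that("orientation is taken from the argument, not guessed", {
  path <- withr::local_tempfile()
  writeLines(c("1,2,3,4", "5,6,7,8"), path)  # 2 rows x 4 cols
  by_col <- read_trials(path, 2, "LFP", orientation = "samples_rows")
  expect_equal(dim(by_col$data), c(2L, 4L))
  by_row <- read_trials(path, 4, "LFP", orientation = "samples_cols")
  expect_equal(dim(by_row$data), c(4L, 2L))
})

test_that("malformed trial files produce located errors", {
  ragged <- withr::local_tempfile()
  writeLines(c("1,2,3", "4,5", "6,7,8"), ragged)
  expect_error(read_trials(ragged, 10, "LFP"), "line 2 has 2 fields")
  bad <- withr::local_tempfile()
  writeLines(c("1,2", "3,oops", "4,5"), bad)
  expect_error(read_trials(bad, 10, "LFP"), "row 2, column 2")
})

test_that("writing an empty trial set is refused", {
  ts <- trial_set(matrix(rnorm(20), nrow = 10), rate = 10, modality = "LFP")
  ts$data <- ts$data[, 0, drop = FALSE]
  expect_error(write_trials(ts, tempfile()), "empty")
})

test_that("an empty config file yields the documented defaults", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(character(), path)
  cfg <- load_config(path)
  expect_equal(cfg$notch_hz, 50)
  expect_equal(cfg$lfp_band, c(0.5, 200))
  expect_equal(cfg$emg_band, c(10, 200))
  expect_equal(cfg$epoch_seconds, 4)
  expect_equal(cfg$composite_weight, 0.5)
})

test_that("config validation rejects out-of-range values naming the key", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines("composite_weight: 1.5", path)
  expect_error(load_config(path), "composite_weight")
  writeLines("lfp_band: [0.5, 1200]", path)
  expect_error(load_config(path), "lfp_band.*Nyquist")
  writeLines("emg_band: [200, 10]", path)
  expect_error(load_config(path), "emg_band")
  writeLines("mystery_knob: 3", path)
  expect_error(load_config(path), "mystery_knob")
  expect_silent(cfg <- run_config(lfp_band = c(0.5, 200), rate = 2000))
})

test_that("config dump and reload is an exact round trip", {
  cfg <- run_config(composite_weight = 0.25, decimate = 4L,
                    spectral_band = c(5, 95), rate = 2000)
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, path)
  expect_equal(load_config(path), cfg)
})
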