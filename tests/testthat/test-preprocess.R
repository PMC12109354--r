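test_that("notch attenuation matches the analytic frequency response", {
  co <- dtw100:::notch_coefficients(50, FS, 30)
  for (f in c(10, 40, 50, 80)) {
    x <- tone_trace(f)
    y <- notch_filter(x, 50, 30)
    expect_equal(rms(y) / rms(x), analytic_gain(co$b, co$a, f, FS),
                 tolerance = 1e-6)
  }
  # >= 20 dB at the notch, passband essentially untouched
  expect_lt(rms(notch_filter(tone_trace(50))) / rms(tone_trace(50)), 0.1)
  expect_gt(rms(notch_filter(tone_trace(10))) / rms(tone_trace(10)), 0.95)
})

test_that("notch filter is linear and validates its frequency", {
  z <- signal_trace(numeric(100), 100, "LFP")
  expect_equal(notch_filter(z, 25, 30)$samples, numeric(100))
  expect_error(notch_filter(tone_trace(10, rate = 100, seconds = 1), 50),
               "Nyquist|rate/2")
  expect_error(notch_filter(tone_trace(10), 50, q = -1), "positive")
})

test_that("bandpass attenuation matches the analytic response at each band", {
  cases <- list(list(band = c(0.5, 200), f = 300),
                list(band = c(0.5, 200), f = 40),
                list(band = c(10, 200), f = 40),
                list(band = c(10, 200), f = 2))
  for (cs in cases) {
    co <- dtw100:::bandpass_coefficients(cs$band, FS)
    pred <- analytic_gain(co$hp$b, co$hp$a, cs$f, FS) *
      analytic_gain(co$lp$b, co$lp$a, cs$f, FS)
    x <- tone_trace(cs$f)
    expect_equal(rms(bandpass_filter(x, cs$band)) / rms(x), pred,
                 tolerance = 1e-6)
  }
  expect_lt(rms(bandpass_filter(tone_trace(300), c(0.5, 200))) /
              rms(tone_trace(300)), 0.1)
  expect_gt(rms(bandpass_filter(tone_trace(40), c(10, 200))) /
              rms(tone_trace(40)), 0.9)
})

test_that("bandpass rejects invalid bands and preserves zeros", {
  z <- signal_trace(numeric(64), 64, "LFP")
  expect_equal(bandpass_filter(z, c(1, 10))$samples, numeric(64))
  expect_error(bandpass_filter(z, c(10, 1)), "low < high")
  expect_error(bandpass_filter(z, c(1, 40)), "Nyquist")
})

test_that("baseline removal kills drift and keeps oscillations", {
  const <- signal_trace(rep(3.7, 2000), 2000, "LFP")
  expect_equal(rms(remove_baseline(const, 0.5)), 0, tolerance = 1e-12)
  drift <- sin(2 * pi * 0.1 * T4)
  tone40 <- sin(2 * pi * 40 * T4)
  out <- remove_baseline(signal_trace(drift + tone40, FS, "LFP"), 1)
  # residual drift after subtracting the 40 Hz part (tone passes ~unchanged)
  resid_drift <- out$samples - tone40
  expect_lt(rms(resid_drift), 0.1 * rms(drift))
  expect_equal(rms(out$samples - drift + drift), rms(tone40),
               tolerance = 0.1)
  expect_error(remove_baseline(const, 0.0005), "at least 3 samples")
  expect_error(remove_baseline(signal_trace(1:10, 10, "LFP"), 5), "exceeds")
})

test_that("the preprocessing chain is length- and phase-preserving", {
  x <- tone_trace(40)
  y <- preprocess_trace(x)
  expect_length(y, length(x))
  bin40 <- 40 * 4 + 1  # 0.25 Hz resolution
  shift <- Arg(fft(y$samples)[bin40]) - Arg(fft(x$samples)[bin40])
  expect_lt(abs(shift), 1e-5)
})

test_that("notch and bandpass commute as linear time-invariant operators", {
  set.seed(7)
  x <- signal_trace(rnorm(8000), FS, "LFP")
  a <- bandpass_filter(notch_filter(x), c(0.5, 200))
  b <- notch_filter(bandpass_filter(x, c(0.5, 200)))
  expect_lt(max(abs(a$samples - b$samples)), 1e-6 * rms(x))
})

test_that("epoch extraction tiles a 4 s inter-trial recording exactly", {
  n_rec <- 31 * 8000
  rec <- signal_trace(seq_len(n_rec), FS, "LFP")
  onsets <- 8000 * (1:30) + 1
  ts <- extract_epochs(rec, onsets, 4, "post_stimulus")
  expect_equal(n_trials(ts), 30)
  # half-open windows: no overlap, no gap
  expect_equal(as.numeric(ts$data), as.numeric(8001:(8000 * 31)))
})

test_that("pre and post windows around one onset are adjacent half-open", {
  rec <- signal_trace(seq_len(100), 10, "LFP")
  pre <- extract_epochs(rec, 51, 2, "pre_stimulus")
  post <- extract_epochs(rec, 51, 2, "post_stimulus")
  expect_equal(as.numeric(pre$data), 31:50)
  expect_equal(as.numeric(post$data), 51:70)
})

test_that("onsets at the recording edge are skipped with a warning", {
  rec <- signal_trace(seq_len(50), 10, "LFP")
  expect_warning(ts <- extract_epochs(rec, c(1, 21), 2, "pre_stimulus"),
                 "skipped")
  expect_equal(n_trials(ts), 1)
  expect_error(suppressWarnings(extract_epochs(rec, 1, 2, "pre_stimulus")),
               "no onset")
})

test_that("trial averaging is the pointwise mean with 1/sqrt(n) noise", {
  m <- cbind(rep(1, 10), rep(3, 10))
  ts <- trial_set(m, rate = 10, modality = "LFP")
  expect_equal(average_trials(ts)$samples, rep(2, 10))
  one <- trial_set(m[, 1, drop = FALSE], rate = 10, modality = "LFP")
  expect_equal(average_trials(one)$samples, m[, 1])
  set.seed(3)
  noise <- trial_set(matrix(rnorm(8000 * 30), 8000), rate = 2000,
                     modality = "LFP")
  expect_equal(sd(average_trials(noise)$samples), 1 / sqrt(30),
               tolerance = 0.2)
})

test_that("the reference pair is the grand mean across subjects", {
  t10 <- function(v, mod) signal_trace(v, 10, mod)
  a <- rnorm(10)
  ref1 <- build_reference(list(t10(a, "LFP")), list(t10(a, "EMG")))
  expect_equal(ref1$lfp_ref$samples, a)
  expect_equal(ref1$n_source_trials, 1)
  ref2 <- build_reference(list(t10(a, "LFP"), t10(-a, "LFP")),
                          list(t10(a, "EMG"), t10(-a, "EMG")))
  expect_equal(ref2$lfp_ref$samples, numeric(10))
  expect_error(
    build_reference(list(t10(a, "LFP"), signal_trace(rnorm(12), 10, "LFP")),
                    list(t10(a, "EMG"), t10(a, "EMG"))),
    "lengths")
  expect_error(build_reference(list(t10(a, "EMG")), list(t10(a, "EMG"))),
               "expected a LFP")
})
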