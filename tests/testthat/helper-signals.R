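# Shared fixtures: everything is generated in code at test time.

FS <- 2000
T4 <- seq(0, 4 - 1 / FS, by = 1 / FS)

tone_trace <- function(freq, rate = FS, seconds = 4, modality = "LFP",
                       amplitude = 1, phase = 0) {
  t <- seq(0, seconds - 1 / rate, by = 1 / rate)
  signal_trace(amplitude * sin(2 * pi * freq * t + phase), rate, modality)
}

rms <- function(x) {
  if (inherits(x, "signal_trace")) x <- x$samples
  sqrt(mean(x^2))
}

# analytic zero-phase gain (squared magnitude) of a b/a filter at freq Hz
analytic_gain <- function(b, a, freq, rate) {
  dtw100:::filter_gain_sq(b, a, 2 * pi * freq / rate)
}

random_pair <- function(max_len = 8) {
  n <- sample.int(max_len, 1)
  m <- sample.int(max_len, 1)
  list(x = round(rnorm(n), 3), y = round(rnorm(m), 3))
}

# tiny but complete study configuration: 1 s epochs at 400 Hz keep the
# quadratic DTW cost negligible while exercising every pipeline stage
tiny_cfg <- function(...) {
  run_config(rate = 400, epoch_seconds = 1, lfp_band = c(0.5, 150),
             emg_band = c(10, 150), baseline_seconds = 0.5, ...)
}

tiny_spec <- function(regime, n_subjects = 3, seed = 42) {
  cohort_spec(regime, n_subjects = n_subjects, n_trials = 5, rate = 400,
              epoch_seconds = 1, seed = seed)
}

tiny_study <- function(seed = 42, cfg = tiny_cfg(), n_subjects = 3) {
  reference <- generate_cohort(tiny_spec("normal", 4, seed))
  pre <- generate_cohort(tiny_spec("bcao_pre", n_subjects, seed + 1))
  post <- generate_cohort(tiny_spec("bcao_post", n_subjects, seed + 2))
  score_cohorts(reference, pre, post, cfg)
}
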