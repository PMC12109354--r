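regime_defaults <- function(regime) {
  # Amplitudes are arbitrary units; only ratios are meaningful. The three
  # regimes encode the qualitative electrophysiology of the study system:
  #  - normal: LFP slightly above EMG, energy concentrated near 40 Hz;
  #  - bcao_pre: global ischemia before stimulation - LFP peak ~3x EMG,
  #    broadband spectrum, markedly increased trial-to-trial variability;
  #  - bcao_post: after ultrasound stimulation - mildly elevated, 40 Hz
  #    concentrated LFP carrying a bimodal envelope, strongly suppressed EMG
  #    (hence the ~100x LFP/EMG peak ratio).
  switch(regime,
    normal = list(lfp_emg_peak_ratio = 1.2, spectral_concentration = 0.7,
                  noise_sigma = 0.3, amp_jitter = 0.05, lfp_peak = 1.2,
                  bimodal = FALSE),
    bcao_pre = list(lfp_emg_peak_ratio = 3, spectral_concentration = 0.2,
                    noise_sigma = 0.6, amp_jitter = 0.35, lfp_peak = 3,
                    bimodal = FALSE),
    bcao_post = list(lfp_emg_peak_ratio = 100, spectral_concentration = 0.7,
                     noise_sigma = 0.3, amp_jitter = 0.05, lfp_peak = 1.5,
                     bimodal = TRUE),
    stop("unknown regime: ", regime))
}

#' Specify a synthetic cohort
#'
#' Defines one experimental regime for the paired LFP/EMG generator. The
#' per-regime defaults encode the descriptive statistics of the study
#' conditions: peak-amplitude ratios of roughly 1.2 (normal), 3 (ischemic,
#' pre-stimulation) and 100 (post-stimulation, EMG suppressed), and 40 Hz
#' spectral concentration of ~0.7 for the normal/post regimes versus ~0.2
#' (broadband) for the pre regime.
#'
#' @param regime `"normal"`, `"bcao_pre"`, or `"bcao_post"`.
#' @param n_subjects number of subjects (animals) in the cohort.
#' @param n_trials stimulation epochs per subject (default 30).
#' @param rate sampling rate in Hz (default 2000).
#' @param epoch_seconds epoch duration (default 4).
#' @param lfp_emg_peak_ratio,spectral_concentration,noise_sigma optional
#'   overrides of the regime defaults. `spectral_concentration` is the
#'   target fraction of LFP power in the 35-45 Hz band; `noise_sigma` the
#'   per-trial white-noise level relative to the modality's peak amplitude.
#' @param seed cohort seed; identical spec + seed give a bit-identical
#'   cohort.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(regime = c("normal", "bcao_pre", "bcao_post"),
                        n_subjects = 9, n_trials = 30, rate = 2000,
                        epoch_seconds = 4, lfp_emg_peak_ratio = NULL,
                        spectral_concentration = NULL, noise_sigma = NULL,
                        seed = 1L) {
  regime <- match.arg(regime)
  def <- regime_defaults(regime)
  spec <- list(
    regime = regime,
    n_subjects = as.integer(n_subjects),
    n_trials = as.integer(n_trials),
    rate = rate,
    epoch_seconds = epoch_seconds,
    lfp_emg_peak_ratio = lfp_emg_peak_ratio %||% def$lfp_emg_peak_ratio,
    spectral_concentration =
      spectral_concentration %||% def$spectral_concentration,
    noise_sigma = noise_sigma %||% def$noise_sigma,
    amp_jitter = def$amp_jitter,
    lfp_peak = def$lfp_peak,
    bimodal = def$bimodal,
    seed = as.integer(seed))
  if (spec$n_subjects < 1L || spec$n_trials < 1L)
    stop("n_subjects and n_trials must be >= 1")
  if (spec$spectral_concentration < 0 || spec$spectral_concentration > 1)
    stop("spectral_concentration must lie in [0, 1]")
  if (spec$lfp_emg_peak_ratio <= 0 || spec$noise_sigma < 0)
    stop("lfp_emg_peak_ratio must be positive and noise_sigma non-negative")
  class(spec) <- "cohort_spec"
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "<cohort_spec> %s: %d subjects x %d trials, %g s @ %g Hz (ratio %g, conc %g, seed %d)\n",
    x$regime, x$n_subjects, x$n_trials, x$epoch_seconds, x$rate,
    x$lfp_emg_peak_ratio, x$spectral_concentration, x$seed))
  invisible(x)
}

# Deterministic seed mixing: subject streams are independent of n_subjects
# and reproducible from (cohort seed, subject index) alone.
subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) * 1009 + as.double(subject_index) * 9973) %%
               2147483629)
}

unit_rms <- function(x) x / sqrt(mean(x^2))

#' Generate one subject's paired LFP/EMG trial sets
#'
#' Signal model: each modality has a subject-level waveform, replicated
#' across trials with mild amplitude jitter and independent white
#' measurement noise per trial. The LFP waveform mixes a stimulus-locked
#' 40 Hz oscillation with band-limited colored noise in proportions set by
#' `spectral_concentration`; the post-stimulation regime multiplies it by a
#' bimodal (two-hump) envelope. The EMG waveform mixes a stimulus-locked
#' 40 Hz-coupled component with band-limited (10-200 Hz) noise amplitude-
#' modulated by the rectified LFP oscillation, and is scaled to
#' `1 / lfp_emg_peak_ratio` of the LFP peak. The ischemic pre-stimulation
#' regime widens the trial amplitude jitter (elevated variability) and the
#' noise floor.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index 1-based subject number; fixes the subject's RNG
#'   stream via a documented mixing of the cohort seed.
#' @return A list with elements `lfp` and `emg`, both [trial_set]s, plus
#'   `subject_id`.
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(subject_seed(spec$seed, subject_index))

  n <- round(spec$epoch_seconds * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  conc <- spec$spectral_concentration
  lfp_peak <- spec$lfp_peak
  emg_peak <- spec$lfp_peak / spec$lfp_emg_peak_ratio

  tone <- sqrt(2) * sin(2 * pi * 40 * t)  # unit RMS, stimulus-locked
  bl <- function(samples, band) {
    co <- bandpass_coefficients(band, spec$rate)
    out <- zero_phase(co$hp$b, co$hp$a, samples)
    zero_phase(co$lp$b, co$lp$a, out)
  }

  lfp_noise <- unit_rms(bl(rnorm(n), c(0.5, 200)))
  lfp_wave <- sqrt(conc) * tone + sqrt(1 - conc) * lfp_noise
  if (spec$bimodal) {
    env <- exp(-(t - 1)^2 / (2 * 0.35^2)) + exp(-(t - 3)^2 / (2 * 0.35^2))
    lfp_wave <- lfp_wave * (env / max(env))
  }
  lfp_wave <- lfp_wave * (lfp_peak / max(abs(lfp_wave)))

  emg_locked <- sqrt(2) * sin(2 * pi * 40 * t + pi / 3)
  coupled <- unit_rms(bl(rnorm(n), c(10, 200)) * (1 + 0.6 * abs(sin(2 * pi * 40 * t))))
  emg_wave <- sqrt(0.5) * emg_locked + sqrt(0.5) * coupled
  emg_wave <- emg_wave * (emg_peak / max(abs(emg_wave)))

  make_trials <- function(wave, peak) {
    amp <- 1 + spec$amp_jitter * rnorm(spec$n_trials)
    noise <- matrix(rnorm(n * spec$n_trials, sd = spec$noise_sigma * peak),
                    nrow = n)
    wave %o% amp + noise
  }
  sid <- sprintf("%s-%02d", spec$regime, subject_index)
  list(
    lfp = trial_set(make_trials(lfp_wave, lfp_peak),
                    epoch_seconds = spec$epoch_seconds, rate = spec$rate,
                    modality = "LFP", label = sid),
    emg = trial_set(make_trials(emg_wave, emg_peak),
                    epoch_seconds = spec$epoch_seconds, rate = spec$rate,
                    modality = "EMG", label = sid),
    subject_id = sid)
}

# save/restore .Random.seed so generation is a pure function of the spec
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_set <- function(seed) {
  if (is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", seed, envir = globalenv())
}

#' Generate a full cohort of subject pairs
#'
#' @param spec a [cohort_spec()].
#' @return A list of `n_subjects` elements, each as returned by
#'   [generate_subject()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lapply(seq_len(spec$n_subjects), function(i) generate_subject(spec, i))
}

power_fraction_40 <- function(trace, band = c(0.5, 200)) {
  sp <- magnitude_spectrum(trace, band)
  inband <- sp$freqs >= 35 & sp$freqs <= 45
  sum(sp$magnitudes[inband]^2) / sum(sp$magnitudes^2)
}

#' Check a generated subject against its regime's design targets
#'
#' Measures, on the trial-averaged traces, the LFP/EMG peak-amplitude ratio
#' and the fraction of LFP power in the 35-45 Hz band, and compares them
#' with the regime's tolerances (normal: ratio 1.05-1.5, fraction >= 0.5;
#' bcao_pre: ratio 2.5-3.5, fraction <= 0.35; bcao_post: ratio 80-120,
#' fraction >= 0.5).
#'
#' @param pair a subject pair from [generate_subject()].
#' @param spec the [cohort_spec()] it was generated from.
#' @return A list: `peak_ratio`, `power_fraction_40`, `ratio_ok`,
#'   `concentration_ok`, `pass`.
#' @export
spectral_check <- function(pair, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  lfp <- average_trials(pair$lfp)
  emg <- average_trials(pair$emg)
  ratio <- max(abs(lfp$samples)) / max(abs(emg$samples))
  frac <- power_fraction_40(lfp)
  lim <- switch(spec$regime,
    normal = list(ratio = c(1.05, 1.5), conc_min = 0.5, conc_max = 1),
    bcao_pre = list(ratio = c(2.5, 3.5), conc_min = 0, conc_max = 0.35),
    bcao_post = list(ratio = c(80, 120), conc_min = 0.5, conc_max = 1))
  ratio_ok <- ratio >= lim$ratio[1] && ratio <= lim$ratio[2]
  conc_ok <- frac >= lim$conc_min && frac <= lim$conc_max
  list(peak_ratio = ratio, power_fraction_40 = frac, ratio_ok = ratio_ok,
       concentration_ok = conc_ok, pass = ratio_ok && conc_ok)
}
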