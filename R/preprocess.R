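#' Design second-order IIR notch coefficients
#'
#' Standard constrained biquad notch: unit gain away from the notch
#' frequency, zero at the notch, bandwidth `freq / q`.
#'
#' @param freq notch frequency in Hz.
#' @param rate sampling rate in Hz.
#' @param q quality factor (default 30).
#' @return list with `b`, `a` polynomial coefficients.
#' @keywords internal
notch_coefficients <- function(freq, rate, q = 30) {
  w0 <- 2 * pi * freq / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# |H(e^{-iw})|^2 of a rational digital filter at angular frequencies w
filter_gain_sq <- function(b, a, w) {
  z <- exp(-1i * w)
  num <- Reduce(function(acc, coef) acc * z + coef, b, accumulate = FALSE)
  den <- Reduce(function(acc, coef) acc * z + coef, a, accumulate = FALSE)
  Mod(num / den)^2
}

zero_phase <- function(b, a, samples) {
  # Zero-phase application of the designed IIR filter: the forward-backward
  # (squared-magnitude) response is applied exactly in the frequency domain
  # over the whole epoch. This keeps the epoch time-aligned (strictly zero
  # phase), makes filtering exactly linear, and avoids the seconds-long edge
  # transients a time-domain recursion would leave with corner frequencies
  # as low as 0.5 Hz on a 4 s epoch.
  n <- length(samples)
  H2 <- filter_gain_sq(b, a, 2 * pi * (0:(n - 1)) / n)
  Re(stats::fft(stats::fft(samples) * H2, inverse = TRUE)) / n
}

#' Remove mains interference with a zero-phase notch filter
#'
#' Applies the zero-phase (forward-backward, squared-magnitude) response of
#' a second-order IIR notch (default 50 Hz, Q = 30), so that epochs stay
#' exactly time-aligned with stimulation onset.
#'
#' @param x a [signal_trace].
#' @param freq notch centre frequency in Hz; must be below Nyquist.
#' @param q quality factor; the -3 dB bandwidth is `freq / q`.
#' @return A [signal_trace] of identical length and rate.
#' @examples
#' t <- seq(0, 1 - 5e-4, by = 5e-4)
#' hum <- signal_trace(sin(2 * pi * 50 * t), 2000, "LFP")
#' clean <- notch_filter(hum)
#' sqrt(mean(clean$samples^2))  # ~0: the 50 Hz tone is removed
#' @export
notch_filter <- function(x, freq = 50, q = 30) {
  stopifnot(inherits(x, "signal_trace"))
  if (!is.finite(freq) || freq <= 0 || freq >= x$rate / 2)
    stop("notch frequency must satisfy 0 < freq < rate/2 = ", x$rate / 2)
  if (!is.finite(q) || q <= 0) stop("notch q must be positive")
  co <- notch_coefficients(freq, x$rate, q)
  dtw100_log("notch_filter: %g Hz, q = %g on %s (%d samples)", freq, q,
             x$modality, length(x$samples))
  signal_trace(zero_phase(co$b, co$a, x$samples), x$rate, x$modality, x$label)
}

moving_average <- function(samples, w) {
  # centred moving average with shrinking windows at the edges, via cumsums
  n <- length(samples)
  half <- w %/% 2
  cs <- cumsum(c(0, samples))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Remove baseline drift by moving-average subtraction
#'
#' Estimates the slowly varying baseline as a centred moving average over
#' `window_seconds` and subtracts it: an adaptive drift remover whose
#' transfer function (1 minus a Dirichlet kernel) passes oscillatory content
#' well above `1 / window_seconds` essentially unchanged.
#'
#' @param x a [signal_trace].
#' @param window_seconds averaging window in seconds (default 1); must span
#'   at least 3 samples.
#' @return A [signal_trace] of identical length and rate.
#' @export
remove_baseline <- function(x, window_seconds = 1) {
  stopifnot(inherits(x, "signal_trace"))
  w <- round(window_seconds * x$rate)
  if (!is.finite(w) || w < 3)
    stop("baseline window must span at least 3 samples, got ", w)
  if (w > length(x$samples))
    stop("baseline window (", w, " samples) exceeds the trace length (",
         length(x$samples), ")")
  dtw100_log("remove_baseline: %g s window on %s", window_seconds, x$modality)
  signal_trace(x$samples - moving_average(x$samples, w), x$rate, x$modality,
               x$label)
}

bandpass_coefficients <- function(band, rate) {
  # Cascade of order-4 Butterworth high-pass and low-pass sections. A direct
  # bandpass design is numerically fragile when low/Nyquist ~ 2.5e-4 (the
  # 0.5 Hz LFP edge at 2 kHz); the cascade keeps the flat Butterworth
  # passband with well-conditioned coefficients.
  nyq <- rate / 2
  hp <- signal::butter(4, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  list(hp = hp, lp = lp)
}

#' Bandpass filter a trace (zero-phase Butterworth)
#'
#' Butterworth bandpass realized as cascaded fourth-order high-pass and
#' low-pass sections, applied zero-phase (forward-backward, i.e. squared
#' magnitude response). The conventional bands are 0.5-200 Hz for LFP and
#' 10-200 Hz for EMG.
#'
#' @param x a [signal_trace].
#' @param band numeric `(low, high)` in Hz with `0 < low < high < rate/2`.
#' @return A [signal_trace] of identical length and rate.
#' @export
bandpass_filter <- function(x, band) {
  stopifnot(inherits(x, "signal_trace"))
  if (length(band) != 2L || anyNA(band) || !(0 < band[1] && band[1] < band[2]))
    stop("band must satisfy 0 < low < high, got (",
         paste(band, collapse = ", "), ")")
  if (band[2] >= x$rate / 2)
    stop("band upper edge (", band[2], ") must be below Nyquist (",
         x$rate / 2, ")")
  co <- bandpass_coefficients(band, x$rate)
  out <- zero_phase(co$hp$b, co$hp$a, x$samples)
  out <- zero_phase(co$lp$b, co$lp$a, out)
  dtw100_log("bandpass_filter: %g-%g Hz on %s", band[1], band[2], x$modality)
  signal_trace(out, x$rate, x$modality, x$label)
}

#' Standard preprocessing chain for one trace
#'
#' Notch (mains), moving-average baseline removal, then the modality's
#' bandpass, in that order; all stages are zero-phase and length-preserving.
#'
#' @param x a [signal_trace].
#' @param cfg a [run_config()].
#' @return The preprocessed [signal_trace].
#' @export
preprocess_trace <- function(x, cfg = run_config()) {
  stopifnot(inherits(x, "signal_trace"), inherits(cfg, "run_config"))
  band <- if (x$modality == "LFP") cfg$lfp_band else cfg$emg_band
  x <- notch_filter(x, cfg$notch_hz, cfg$notch_q)
  x <- remove_baseline(x, cfg$baseline_seconds)
  bandpass_filter(x, band)
}

#' Cut stimulation-locked epochs from a continuous recording
#'
#' Windows are half-open in samples: a post-stimulus epoch is
#' `[onset, onset + N)` (it contains the 300 ms stimulation burst), a
#' pre-stimulus epoch is `[onset - N, onset)`. Onsets whose window would run
#' past either end of the recording are skipped with a warning.
#'
#' @param x a [signal_trace] holding the continuous recording.
#' @param onsets integer sample indices (1-based) of stimulation onsets.
#' @param epoch_seconds epoch duration in seconds.
#' @param alignment `"post_stimulus"` or `"pre_stimulus"`.
#' @return A [trial_set] with one trial per usable onset.
#' @export
extract_epochs <- function(x, onsets, epoch_seconds,
                           alignment = c("post_stimulus", "pre_stimulus")) {
  stopifnot(inherits(x, "signal_trace"))
  alignment <- match.arg(alignment)
  n_epoch <- round(epoch_seconds * x$rate)
  if (n_epoch < 2) stop("epoch must span at least 2 samples")
  onsets <- as.integer(onsets)
  n <- length(x$samples)
  starts <- if (alignment == "post_stimulus") onsets else onsets - n_epoch
  ok <- starts >= 1L & (starts + n_epoch - 1L) <= n
  if (any(!ok)) {
    warning(sum(!ok), " onset(s) too close to the recording edge were skipped",
            call. = FALSE)
    starts <- starts[ok]
  }
  if (length(starts) == 0L)
    stop("no onset admits a full ", epoch_seconds, " s window")
  mat <- vapply(starts, function(s) x$samples[s:(s + n_epoch - 1L)],
                numeric(n_epoch))
  trial_set(matrix(mat, nrow = n_epoch), epoch_seconds = epoch_seconds,
            alignment = alignment, rate = x$rate, modality = x$modality,
            label = x$label)
}

#' Average repeated trials by superposition
#'
#' Pointwise arithmetic mean across the epochs of a trial set, the classic
#' evoked-response average: stimulus-locked structure is preserved while
#' trial-independent noise shrinks as `1/sqrt(n_trials)`.
#'
#' @param t a [trial_set].
#' @return A [signal_trace] of one epoch length.
#' @export
average_trials <- function(t) {
  stopifnot(inherits(t, "trial_set"))
  if (ncol(t$data) < 1L) stop("cannot average an empty trial set")
  signal_trace(rowMeans(t$data), t$rate, t$modality, t$label)
}

#' Build the healthy-reference signal pair
#'
#' Grand mean over the normal cohort: each subject's trials are averaged,
#' then the subject averages are averaged per modality. The resulting LFP
#' and EMG traces are the baseline every scored sample is warped against.
#'
#' @param lfp_sets list of LFP [trial_set]s (or already-averaged
#'   [signal_trace]s), one per subject.
#' @param emg_sets matching list of EMG sets.
#' @return An object of class `reference_pair` with fields `lfp_ref`,
#'   `emg_ref`, `n_source_trials` (number of contributing subjects).
#' @export
build_reference <- function(lfp_sets, emg_sets) {
  if (length(lfp_sets) == 0L || length(emg_sets) == 0L)
    stop("reference construction needs at least one subject per modality")
  avg1 <- function(s, modality) {
    if (inherits(s, "trial_set")) s <- average_trials(s)
    stopifnot(inherits(s, "signal_trace"))
    if (s$modality != modality)
      stop("expected a ", modality, " input, got ", s$modality)
    s
  }
  lfp <- lapply(lfp_sets, avg1, "LFP")
  emg <- lapply(emg_sets, avg1, "EMG")
  grand <- function(traces, modality) {
    lens <- vapply(traces, length, integer(1))
    if (length(unique(lens)) != 1L)
      stop("mismatched ", modality, " trace lengths across subjects: ",
           paste(unique(lens), collapse = ", "))
    rates <- unique(vapply(traces, `[[`, numeric(1), "rate"))
    if (length(rates) != 1L) stop("mismatched sampling rates across subjects")
    m <- vapply(traces, `[[`, numeric(lens[1]), "samples")
    signal_trace(rowMeans(matrix(m, nrow = lens[1])), rates, modality,
                 "reference")
  }
  lfp_ref <- grand(lfp, "LFP")
  emg_ref <- grand(emg, "EMG")
  if (length(lfp_ref) != length(emg_ref) || lfp_ref$rate != emg_ref$rate)
    stop("LFP and EMG references must share length and rate")
  structure(list(lfp_ref = lfp_ref, emg_ref = emg_ref,
                 n_source_trials = length(lfp)),
            class = "reference_pair")
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf("<reference_pair> %d subjects, %d samples @ %g Hz\n",
              x$n_source_trials, length(x$lfp_ref), x$lfp_ref$rate))
  invisible(x)
}
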