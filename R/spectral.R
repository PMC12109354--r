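#' One-sided magnitude spectrum of a trace
#'
#' Single full-epoch discrete Fourier transform (no segmenting, no taper),
#' so bin frequencies are exact multiples of `rate / N` (0.25 Hz for a 4 s
#' epoch at 2 kHz). Magnitudes are amplitude-scaled: a unit-amplitude
#' sinusoid sitting on a bin yields magnitude 1 at that bin (DC and Nyquist
#' bins carry weight 1 instead of 2).
#'
#' @param x a [signal_trace].
#' @param band optional `(low, high)` Hz restriction with
#'   `0 < low < high < rate/2`; `NULL` keeps the full one-sided spectrum
#'   including DC (and Nyquist for even lengths).
#' @return An object of class `spectrum_trace`: `freqs`, `magnitudes`,
#'   `modality`, `resolution_hz`.
#' @examples
#' t <- seq(0, 4 - 5e-4, by = 5e-4)
#' sp <- magnitude_spectrum(signal_trace(sin(2 * pi * 40 * t), 2000, "LFP"))
#' sp$freqs[which.max(sp$magnitudes)]  # 40
#' @export
magnitude_spectrum <- function(x, band = NULL) {
  stopifnot(inherits(x, "signal_trace"))
  n <- length(x$samples)
  res <- x$rate / n
  half <- floor(n / 2)
  raw <- Mod(stats::fft(x$samples))[1:(half + 1)]
  w <- rep(2, half + 1)
  w[1] <- 1
  if (n %% 2 == 0) w[half + 1] <- 1
  mags <- raw * w / n
  freqs <- (0:half) * res
  if (!is.null(band)) {
    if (length(band) != 2L || !(0 < band[1] && band[1] < band[2]))
      stop("band must satisfy 0 < low < high")
    if (band[2] >= x$rate / 2)
      stop("band upper edge (", band[2], ") must be below Nyquist (",
           x$rate / 2, ")")
    keep <- freqs >= band[1] & freqs <= band[2]
    freqs <- freqs[keep]
    mags <- mags[keep]
  }
  structure(list(freqs = freqs, magnitudes = mags, modality = x$modality,
                 resolution_hz = res),
            class = "spectrum_trace")
}

#' @export
print.spectrum_trace <- function(x, ...) {
  cat(sprintf("<spectrum_trace> %s: %d bins, %g-%g Hz @ %g Hz resolution\n",
              x$modality, length(x$freqs), min(x$freqs), max(x$freqs),
              x$resolution_hz))
  invisible(x)
}

#' Write a spectrum as two-column delimited text
#'
#' @param sp a `spectrum_trace`.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path, sep = ",") {
  stopifnot(inherits(sp, "spectrum_trace"))
  write.table(
    data.frame(freq_hz = sprintf("%.17g", sp$freqs),
               magnitude = sprintf("%.17g", sp$magnitudes)),
    path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

decimate_bins <- function(sp, factor) {
  if (factor <= 1L) return(sp)
  n <- length(sp$freqs)
  grp <- (seq_len(n) - 1L) %/% factor
  sp$freqs <- as.numeric(tapply(sp$freqs, grp, mean))
  sp$magnitudes <- as.numeric(tapply(sp$magnitudes, grp, mean))
  sp$resolution_hz <- sp$resolution_hz * factor
  sp
}

spectrum_values <- function(sp, scale) {
  switch(scale,
         magnitude = sp$magnitudes,
         power = sp$magnitudes^2,
         db = 20 * log10(pmax(sp$magnitudes, 1e-12)))
}

spectral_band_for <- function(cfg, modality) {
  if (!is.null(cfg$spectral_band)) cfg$spectral_band
  else if (modality == "LFP") cfg$lfp_band else cfg$emg_band
}

spectral_norm_distance <- function(trace, ref_trace, cfg, bin_decimate = 1L,
                                   scale = "magnitude") {
  band <- spectral_band_for(cfg, trace$modality)
  sp <- decimate_bins(magnitude_spectrum(trace, band), bin_decimate)
  rp <- decimate_bins(magnitude_spectrum(ref_trace, band), bin_decimate)
  normalize_distance(dtw_distance(spectrum_values(sp, scale),
                                  spectrum_values(rp, scale),
                                  keep_path = FALSE))
}

#' Score one subject's trace pair against the reference (frequency domain)
#'
#' The FRE pathway: computes the one-sided magnitude spectra of the sample
#' and reference traces over the configured band per modality, then applies
#' the identical DTW, normalization, percentage-score and composite chain as
#' [score_sample()]. The frequency domain has its own coefficient `A`
#' because spectral distances live on a different scale than time-domain
#' distances.
#'
#' @inheritParams score_sample
#' @param bin_decimate average this many adjacent bins before DTW (default 1
#'   = off); bounds the spectral DTW cost on long epochs.
#' @param scale representation fed to DTW: `"magnitude"` (default),
#'   `"power"`, or `"db"`.
#' @return A `score_card` with `domain = "frequency"`.
#' @export
score_sample_spectral <- function(lfp, emg, ref, cfg = run_config(),
                                  phase = "pre", sample_id = lfp$label,
                                  bin_decimate = 1L,
                                  scale = c("magnitude", "power", "db")) {
  scale <- match.arg(scale)
  stopifnot(inherits(ref, "reference_pair"), inherits(cfg, "run_config"))
  if (is.null(cfg$coefficient_A))
    stop("cfg$coefficient_A is unset; calibrate it (see calibrate_A) or use ",
         "score_cohorts() which calibrates on the pre cohort")
  for (nm in c("lfp", "emg")) {
    tr <- if (nm == "lfp") lfp else emg
    rf <- if (nm == "lfp") ref$lfp_ref else ref$emg_ref
    if (length(tr) != length(rf) || tr$rate != rf$rate)
      stop(toupper(nm), " trace and reference differ in length or rate")
  }
  d_lfp <- spectral_norm_distance(lfp, ref$lfp_ref, cfg, bin_decimate, scale)
  d_emg <- spectral_norm_distance(emg, ref$emg_ref, cfg, bin_decimate, scale)
  new_score_card(sample_id,
                 dtw100_score(d_lfp, cfg$coefficient_A),
                 dtw100_score(d_emg, cfg$coefficient_A),
                 cfg$composite_weight, "frequency", phase, cfg$coefficient_A)
}
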