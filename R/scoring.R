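#' Convert a normalized DTW distance into a percentage score
#'
#' `100 * (1 - A * norm_distance)`, clamped to \[0, 100\]: a sample identical
#' to the reference scores 100, and scores fall linearly with warping
#' distance until the clamp. `A` is the adjustable scale coefficient; see
#' [calibrate_A()] for the default calibration policy.
#'
#' @param norm_distance non-negative normalized DTW distance(s).
#' @param coefficient_A positive scale coefficient.
#' @return Score(s) in \[0, 100\].
#' @examples
#' dtw100_score(0, 3)      # 100
#' dtw100_score(1 / 3, 3)  # 0
#' @export
dtw100_score <- function(norm_distance, coefficient_A) {
  if (!is.numeric(coefficient_A) || length(coefficient_A) != 1L ||
      !is.finite(coefficient_A) || coefficient_A <= 0)
    stop("coefficient_A must be a single positive number")
  if (any(!is.finite(norm_distance)) || any(norm_distance < 0))
    stop("norm_distance must be finite and non-negative")
  pmin(pmax(100 * (1 - coefficient_A * norm_distance), 0), 100)
}

#' Calibrate the scoring coefficient A
#'
#' Chooses `A` so that the largest normalized distance in a calibration set
#' maps exactly to `floor_score`: `A = (1 - floor_score/100) / max(d)`.
#' Calibrating on the pre-stimulation cohort with floor 0 anchors the score
#' scale to the worst observed impairment, making runs self-contained and
#' deterministic. Time- and frequency-domain distances live on different
#' scales, so each domain is calibrated separately.
#'
#' @param norm_distances normalized distances of the calibration cohort; at
#'   least one must be positive.
#' @param floor_score score assigned to the largest distance (default 0;
#'   must be in \[0, 100)).
#' @return The coefficient `A` (positive scalar).
#' @examples
#' calibrate_A(c(0.2, 0.4), floor_score = 50)  # 1.25
#' @export
calibrate_A <- function(norm_distances, floor_score = 0) {
  if (length(norm_distances) < 1L || any(!is.finite(norm_distances)) ||
      any(norm_distances < 0))
    stop("norm_distances must be non-negative finite values")
  if (!is.finite(floor_score) || floor_score < 0 || floor_score >= 100)
    stop("floor_score must lie in [0, 100)")
  mx <- max(norm_distances)
  if (mx <= 0)
    stop("all calibration distances are zero; A is undefined")
  (1 - floor_score / 100) / mx
}

#' Weighted composite of the LFP and EMG scores
#'
#' `weight * lfp + (1 - weight) * emg`; the conventional weighting is equal
#' (0.5/0.5).
#'
#' @param lfp_score,emg_score per-modality scores in \[0, 100\].
#' @param weight LFP weight in \[0, 1\] (default 0.5).
#' @return The composite score.
#' @export
composite_score <- function(lfp_score, emg_score, weight = 0.5) {
  for (s in list(lfp_score, emg_score))
    if (any(!is.finite(s)) || any(s < 0) || any(s > 100))
      stop("scores must lie in [0, 100]")
  if (!is.finite(weight) || weight < 0 || weight > 1)
    stop("weight must lie in [0, 1]")
  weight * lfp_score + (1 - weight) * emg_score
}

new_score_card <- function(sample_id, lfp_score, emg_score, weight, domain,
                           phase, coefficient_A) {
  structure(
    list(sample_id = sample_id, lfp_score = lfp_score, emg_score = emg_score,
         composite = composite_score(lfp_score, emg_score, weight),
         domain = domain, phase = phase, coefficient_A = coefficient_A),
    class = "score_card")
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("<score_card> %s (%s, %s): LFP %.1f | EMG %.1f | composite %.1f (A = %.4g)\n",
              x$sample_id, x$domain, x$phase, x$lfp_score, x$emg_score,
              x$composite, x$coefficient_A))
  invisible(x)
}

#' Flatten score cards into a table
#'
#' @param cards a list of `score_card` objects (or a single one).
#' @return A data.frame with columns `sample_id`, `phase`, `domain`,
#'   `lfp_score`, `emg_score`, `composite`, `coefficient_A`.
#' @export
score_table <- function(cards) {
  if (inherits(cards, "score_card")) cards <- list(cards)
  do.call(rbind, lapply(cards, function(c)
    data.frame(sample_id = c$sample_id, phase = c$phase, domain = c$domain,
               lfp_score = c$lfp_score, emg_score = c$emg_score,
               composite = c$composite, coefficient_A = c$coefficient_A,
               stringsAsFactors = FALSE)))
}

sample_norm_distance <- function(trace, ref_trace, decimate = 1L) {
  a <- trace$samples
  b <- ref_trace$samples
  if (decimate > 1L) {
    idx <- seq(1L, length(a), by = decimate)
    a <- a[idx]
    idx <- seq(1L, length(b), by = decimate)
    b <- b[idx]
  }
  normalize_distance(dtw_distance(a, b, keep_path = FALSE))
}

#' Score one subject's trace pair against the reference (time domain)
#'
#' Runs [dtw_distance()] and [normalize_distance()] per modality against the
#' matching reference trace, converts to percentage scores with
#' [dtw100_score()], and combines them with [composite_score()].
#'
#' @param lfp,emg the subject's preprocessed, trial-averaged
#'   [signal_trace]s.
#' @param ref a `reference_pair` from [build_reference()].
#' @param cfg a [run_config()]; `cfg$coefficient_A` must be set here (the
#'   pipeline calibrates it cohort-wide, see [score_cohorts()]).
#' @param phase `"pre"` or `"post"` stimulation tag.
#' @param sample_id identifier recorded on the card.
#' @return A `score_card` with `domain = "time"`.
#' @export
score_sample <- function(lfp, emg, ref, cfg = run_config(), phase = "pre",
                         sample_id = lfp$label) {
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
  d_lfp <- sample_norm_distance(lfp, ref$lfp_ref, cfg$decimate)
  d_emg <- sample_norm_distance(emg, ref$emg_ref, cfg$decimate)
  new_score_card(sample_id,
                 dtw100_score(d_lfp, cfg$coefficient_A),
                 dtw100_score(d_emg, cfg$coefficient_A),
                 cfg$composite_weight, "time", phase, cfg$coefficient_A)
}
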