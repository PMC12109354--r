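#' Construct a single-channel signal trace
#'
#' The elementary container of the package: one uniformly sampled channel of
#' electrophysiology, either a local field potential (LFP) from motor cortex
#' or an electromyogram (EMG) from tail muscle. Amplitudes are treated as
#' arbitrary-but-consistent units (nominally microvolts) and are never
#' rescaled; scoring only requires that sample and reference share units.
#'
#' @param samples numeric vector of at least 2 samples.
#' @param rate sampling rate in Hz (> 0).
#' @param modality `"LFP"` or `"EMG"`.
#' @param label free-text subject/sample identifier.
#' @return An object of class `signal_trace`.
#' @examples
#' tr <- signal_trace(sin(2 * pi * 40 * seq(0, 1, by = 5e-4)), 2000, "LFP")
#' tr
#' @export
signal_trace <- function(samples, rate, modality = c("LFP", "EMG"),
                         label = "") {
  modality <- match.arg(modality)
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("signal_trace needs at least 2 samples, got ", length(samples))
  if (!is.finite(rate) || rate <= 0)
    stop("sampling rate must be a positive number, got ", rate)
  if (anyNA(samples))
    stop("samples contain missing values")
  structure(
    list(samples = samples, rate = as.numeric(rate), modality = modality,
         label = as.character(label)),
    class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %s%s: %d samples @ %g Hz (%.3f s)\n",
              x$modality, if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.signal_trace <- function(x) length(x$samples)

#' Construct a stack of equal-length stimulation epochs
#'
#' Repeated stimulation trials from one subject and one modality, all cut to
#' the same epoch duration at the same rate, stored as a samples-by-trials
#' matrix.
#'
#' @param trials list of [signal_trace] objects, or a numeric matrix with one
#'   column per trial (then `rate` and `modality` are required).
#' @param epoch_seconds epoch duration in seconds; must equal
#'   `n_samples / rate`.
#' @param alignment `"post_stimulus"` (epoch starts at stimulation onset) or
#'   `"pre_stimulus"` (epoch ends at onset).
#' @param rate,modality,label used when `trials` is a matrix.
#' @return An object of class `trial_set` with fields `data` (samples x
#'   trials matrix), `rate`, `modality`, `epoch_seconds`, `alignment`,
#'   `label`.
#' @export
trial_set <- function(trials, epoch_seconds = NULL,
                      alignment = c("post_stimulus", "pre_stimulus"),
                      rate = NULL, modality = NULL, label = "") {
  alignment <- match.arg(alignment)
  if (is.list(trials)) {
    if (length(trials) == 0L) stop("trial_set needs at least one trial")
    stopifnot(all(vapply(trials, inherits, logical(1), "signal_trace")))
    lens <- vapply(trials, function(t) length(t$samples), integer(1))
    if (length(unique(lens)) != 1L)
      stop("all trials must have identical length; got lengths ",
           paste(unique(lens), collapse = ", "))
    rates <- unique(vapply(trials, `[[`, numeric(1), "rate"))
    if (length(rates) != 1L) stop("all trials must share one sampling rate")
    mods <- unique(vapply(trials, `[[`, character(1), "modality"))
    if (length(mods) != 1L) stop("all trials must share one modality")
    data <- vapply(trials, `[[`, numeric(lens[1]), "samples")
    data <- matrix(data, nrow = lens[1])
    rate <- rates
    modality <- mods
  } else {
    data <- as.matrix(trials)
    storage.mode(data) <- "double"
    if (is.null(rate) || is.null(modality))
      stop("rate and modality are required when trials is a matrix")
    modality <- match.arg(modality, c("LFP", "EMG"))
    if (nrow(data) < 2L) stop("trials need at least 2 samples each")
    if (anyNA(data)) stop("trial matrix contains missing values")
  }
  if (is.null(epoch_seconds)) epoch_seconds <- nrow(data) / rate
  if (round(epoch_seconds * rate) != nrow(data))
    stop(sprintf("epoch_seconds (%g) x rate (%g) = %g does not match %d samples",
                 epoch_seconds, rate, epoch_seconds * rate, nrow(data)))
  structure(
    list(data = data, rate = as.numeric(rate), modality = modality,
         epoch_seconds = as.numeric(epoch_seconds), alignment = alignment,
         label = as.character(label)),
    class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %s: %d trials x %d samples @ %g Hz (%g s epochs, %s)\n",
              x$modality, ncol(x$data), nrow(x$data), x$rate,
              x$epoch_seconds, x$alignment))
  invisible(x)
}

#' Number of trials in a trial set
#' @param t a [trial_set].
#' @return integer count.
#' @export
n_trials <- function(t) {
  stopifnot(inherits(t, "trial_set"))
  ncol(t$data)
}

detect_sep <- function(first_line) {
  if (grepl("\t", first_line)) "\t" else if (grepl(",", first_line)) "," else " "
}

#' Read a trial matrix from delimited text
#'
#' Parses a comma- or tab-delimited text file holding one subject's repeated
#' stimulation epochs. The default orientation is one column per trial and
#' one row per sample; the orientation is an explicit argument, never
#' guessed from the shape.
#'
#' @param path file path.
#' @param rate sampling rate in Hz.
#' @param modality `"LFP"` or `"EMG"`.
#' @param orientation `"samples_rows"` (default: rows are samples, columns are
#'   trials) or `"samples_cols"` (transposed).
#' @param alignment epoch alignment tag, see [trial_set].
#' @param label subject identifier; defaults to the file name.
#' @return A [trial_set].
#' @seealso [write_trials()]
#' @export
read_trials <- function(path, rate, modality = c("LFP", "EMG"),
                        orientation = c("samples_rows", "samples_cols"),
                        alignment = c("post_stimulus", "pre_stimulus"),
                        label = NULL) {
  modality <- match.arg(modality)
  orientation <- match.arg(orientation)
  alignment <- match.arg(alignment)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- detect_sep(first)
  nf <- count.fields(path, sep = sep)
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1])[1]
    stop(sprintf("ragged input in %s: line %d has %d fields, expected %d",
                 path, bad, nf[bad], nf[1]))
  }
  header <- suppressWarnings(
    anyNA(as.numeric(strsplit(first, sep, fixed = TRUE)[[1]])))
  raw <- read.table(path, sep = sep, header = header,
                    colClasses = "character", check.names = FALSE)
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell in %s at row %d, column %d: '%s'",
                 path, idx[1] + header, idx[2], as.matrix(raw)[idx[1], idx[2]]))
  }
  if (orientation == "samples_cols") mat <- t(mat)
  trial_set(mat, rate = rate, modality = modality, alignment = alignment,
            label = if (is.null(label)) basename(path) else label)
}

#' Write a trial matrix as delimited text
#'
#' One column per trial, one row per sample, full double precision (17
#' significant digits) so a [read_trials()] round trip reproduces the samples
#' to text-representation accuracy.
#'
#' @param t a [trial_set].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(t, path, sep = ",") {
  stopifnot(inherits(t, "trial_set"))
  if (ncol(t$data) < 1L) stop("refusing to write an empty trial set")
  txt <- apply(t$data, 2, function(col) sprintf("%.17g", col))
  txt <- matrix(txt, nrow = nrow(t$data))
  lines <- apply(txt, 1, paste, collapse = sep)
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

default_config <- function() {
  list(
    rate = 2000,                 # Hz; acquisition rate for LFP and EMG
    notch_hz = 50,               # mains interference
    notch_q = 30,                # notch quality factor (~1.7 Hz bandwidth)
    lfp_band = c(0.5, 200),      # Hz
    emg_band = c(10, 200),       # Hz
    baseline_seconds = 1,        # moving-average drift window
    epoch_seconds = 4,
    coefficient_A = NULL,        # NULL = calibrate on the pre cohort
    composite_weight = 0.5,      # LFP weight in the composite score
    spectral_band = NULL,        # NULL = reuse the modality bandpass edges
    decimate = 1L,               # time-domain decimation before DTW
    seed = 1L
  )
}

validate_config <- function(cfg) {
  num1 <- function(key, lo = -Inf, hi = Inf, null_ok = FALSE) {
    v <- cfg[[key]]
    if (is.null(v)) {
      if (null_ok) return(invisible(NULL))
      stop("config key '", key, "' is missing")
    }
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < lo || v > hi)
      stop(sprintf("config key '%s' must be a number in [%g, %g], got %s",
                   key, lo, hi, paste(v, collapse = ",")))
  }
  num1("rate", lo = 1e-9)
  nyq <- cfg$rate / 2
  num1("notch_hz", lo = 1e-9)
  if (cfg$notch_hz >= nyq)
    stop("config key 'notch_hz' (", cfg$notch_hz, ") must be below Nyquist (",
         nyq, ")")
  num1("notch_q", lo = 1e-9)
  for (key in c("lfp_band", "emg_band", "spectral_band")) {
    b <- cfg[[key]]
    if (is.null(b) && key == "spectral_band") next
    if (!is.numeric(b) || length(b) != 2L || anyNA(b))
      stop("config key '", key, "' must be two numbers (low, high)")
    if (!(0 < b[1] && b[1] < b[2]))
      stop("config key '", key, "' must satisfy 0 < low < high, got (",
           b[1], ", ", b[2], ")")
    if (b[2] >= nyq)
      stop("config key '", key, "' upper edge (", b[2],
           ") must be below Nyquist (", nyq, ")")
  }
  num1("baseline_seconds", lo = 1e-9)
  num1("epoch_seconds", lo = 1e-9)
  num1("coefficient_A", lo = 1e-12, null_ok = TRUE)
  num1("composite_weight", lo = 0, hi = 1)
  num1("decimate", lo = 1)
  num1("seed")
  cfg$decimate <- as.integer(cfg$decimate)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "run_config"
  cfg
}

#' Build a run configuration
#'
#' All tunable parameters of the pipeline with their defaults: 50 Hz notch,
#' 0.5-200 Hz LFP and 10-200 Hz EMG bandpass, 4 s epochs, 1 s baseline
#' window, equal 0.5/0.5 composite weighting, and a scoring coefficient `A`
#' that is calibrated on the pre-stimulation cohort unless pinned here.
#'
#' @param ... named overrides of the defaults (see [load_config()] for the
#'   full key list).
#' @return A validated `run_config` object (a named list).
#' @examples
#' cfg <- run_config(composite_weight = 0.6)
#' cfg$lfp_band
#' @export
run_config <- function(...) {
  cfg <- default_config()
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-17s %s\n", k,
                if (is.null(v)) "(auto)" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Load a run configuration from a flat key-value file
#'
#' The file is flat YAML (`key: value`; band edges as two-element sequences
#' or `"low, high"` strings). Missing keys take the package defaults; an
#' empty file yields the full default configuration. Values are validated
#' (band edges must satisfy `0 < low < high < rate/2`, the composite weight
#' must lie in \[0, 1\]).
#'
#' @param path path to the configuration file.
#' @return A validated `run_config`.
#' @seealso [write_config()], [run_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must contain key: value pairs")
  cfg <- default_config()
  bad <- setdiff(names(raw), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in names(raw)) {
    v <- raw[[k]]
    if (is.list(v)) v <- unlist(v)
    if (is.character(v) && length(v) == 1L && grepl(",", v))
      v <- as.numeric(trimws(strsplit(v, ",")[[1]]))
    cfg[[k]] <- v
  }
  validate_config(cfg)
}

#' Write a run configuration to a flat key-value file
#'
#' Inverse of [load_config()]: a config dumped and re-loaded reproduces
#' itself exactly.
#'
#' @param cfg a `run_config`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(unclass(out), path)
  invisible(path)
}
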