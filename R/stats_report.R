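#' Mean and sample standard deviation of a score set
#'
#' @param scores numeric vector; at least 2 values.
#' @return Named vector `c(mean, sd)` (sd uses the n-1 denominator).
#' @export
summarize_scores <- function(scores) {
  if (length(scores) < 2L)
    stop("need at least 2 values for a standard deviation")
  if (anyNA(scores)) stop("scores contain missing values")
  c(mean = mean(scores), sd = sd(scores))
}

#' Paired two-tailed t-test between pre- and post-stimulation scores
#'
#' Tests whether the within-subject score change differs from zero:
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = post - pre`, with `n - 1` degrees of freedom. If the differences
#' have zero variance the t statistic is undefined; the p-value is then
#' reported as exactly 0 (all differences equal and non-zero) or 1 (pre
#' equals post), with a warning.
#'
#' @param pre,post equal-length score vectors paired by subject, `n >= 2`.
#' @param domain tag recorded on the result (`"time"` or `"frequency"`).
#' @return An object of class `group_comparison` with the score summaries,
#'   paired mean/sd increase, `t_statistic`, `p_value`, and `n`.
#' @export
paired_t_test <- function(pre, post, domain = "time") {
  if (length(pre) != length(post))
    stop("pre and post must be paired: lengths ", length(pre), " vs ",
         length(post))
  n <- length(pre)
  if (n < 2L) stop("paired t-test needs at least 2 pairs")
  if (anyNA(pre) || anyNA(post)) stop("scores contain missing values")
  d <- post - pre
  if (sd(d) == 0) {
    warning("zero variance of paired differences; t statistic undefined",
            call. = FALSE)
    t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    p <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- stats::t.test(post, pre, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(domain = domain, pre_scores = pre, post_scores = post,
         mean_pre = mean(pre), sd_pre = sd(pre),
         mean_post = mean(post), sd_post = sd(post),
         mean_increase = mean(d), sd_increase = sd(d),
         t_statistic = t_stat, p_value = p, n = n),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s domain (n = %d pairs)\n  pre  %.1f +/- %.1f\n  post %.1f +/- %.1f\n  increase %.1f +/- %.1f, t = %.3f, p = %.3g\n",
    x$domain, x$n, x$mean_pre, x$sd_pre, x$mean_post, x$sd_post,
    x$mean_increase, x$sd_increase, x$t_statistic, x$p_value))
  invisible(x)
}

comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(c)
    data.frame(domain = c$domain, n = c$n, mean_pre = c$mean_pre,
               sd_pre = c$sd_pre, mean_post = c$mean_post,
               sd_post = c$sd_post, mean_increase = c$mean_increase,
               sd_increase = c$sd_increase, t_statistic = c$t_statistic,
               p_value = c$p_value, stringsAsFactors = FALSE)))
}

# Average a subject's trials, then preprocess the average. Every
# preprocessing stage is linear and time-invariant, so this equals averaging
# the preprocessed trials exactly, at 1/n_trials of the filtering cost.
prep_subject <- function(pair, cfg) {
  list(lfp = preprocess_trace(average_trials(pair$lfp), cfg),
       emg = preprocess_trace(average_trials(pair$emg), cfg),
       subject_id = pair$subject_id %||% pair$lfp$label)
}

#' Score pre/post cohorts against a reference cohort (in-memory pipeline)
#'
#' The full evaluation: preprocesses every subject (trial average, notch,
#' baseline removal, modality bandpass), builds the grand-mean reference
#' pair from the reference cohort, computes time-domain and frequency-domain
#' normalized DTW distances, calibrates the scoring coefficient `A` per
#' domain on the pre-stimulation cohort (floor score 0) unless
#' `cfg$coefficient_A` pins it, converts distances to percentage score
#' cards, and runs the paired pre/post t-test per domain on the composite
#' scores.
#'
#' @param reference list of reference-cohort subject pairs (each a list with
#'   `lfp` and `emg` [trial_set]s, e.g. from [generate_cohort()] or read via
#'   a manifest).
#' @param pre,post lists of subject pairs for the pre- and post-stimulation
#'   phases, paired by position; may be empty.
#' @param cfg a [run_config()]. `cfg$decimate > 1` subsamples the
#'   time-domain traces before DTW (both sample and reference) to bound the
#'   quadratic cost.
#' @param bin_decimate spectral bin decimation passed to the frequency
#'   pathway (default 1 = full resolution).
#' @param domain `"both"` (default), `"time"`, or `"frequency"`.
#' @return A list: `scores` (data.frame of all score cards), `comparisons`
#'   (data.frame, one row per domain with paired t results), `A` (named
#'   vector of the coefficients used), `reference` (the `reference_pair`),
#'   `cards` (the raw `score_card` list).
#' @export
score_cohorts <- function(reference, pre, post, cfg = run_config(),
                          bin_decimate = 1L,
                          domain = c("both", "time", "frequency")) {
  domain <- match.arg(domain)
  stopifnot(inherits(cfg, "run_config"))
  if (length(pre) != length(post) && length(pre) > 0 && length(post) > 0)
    stop("pre and post cohorts must be paired by subject: ", length(pre),
         " vs ", length(post))
  dtw100_log("preprocessing %d reference + %d pre + %d post subjects",
             length(reference), length(pre), length(post))
  ref_prep <- lapply(reference, prep_subject, cfg = cfg)
  ref <- build_reference(lapply(ref_prep, `[[`, "lfp"),
                         lapply(ref_prep, `[[`, "emg"))
  pre_prep <- lapply(pre, prep_subject, cfg = cfg)
  post_prep <- lapply(post, prep_subject, cfg = cfg)

  domains <- if (domain == "both") c("time", "frequency") else domain
  dist_fun <- function(subj, dom) {
    if (dom == "time")
      c(lfp = sample_norm_distance(subj$lfp, ref$lfp_ref, cfg$decimate),
        emg = sample_norm_distance(subj$emg, ref$emg_ref, cfg$decimate))
    else
      c(lfp = spectral_norm_distance(subj$lfp, ref$lfp_ref, cfg, bin_decimate),
        emg = spectral_norm_distance(subj$emg, ref$emg_ref, cfg, bin_decimate))
  }

  cards <- list()
  A_used <- c()
  for (dom in domains) {
    d_pre <- lapply(pre_prep, dist_fun, dom = dom)
    d_post <- lapply(post_prep, dist_fun, dom = dom)
    A <- cfg$coefficient_A
    if (is.null(A)) {
      if (length(d_pre) == 0L)
        stop("cannot calibrate A without a pre-stimulation cohort; ",
             "set cfg$coefficient_A explicitly")
      A <- calibrate_A(unlist(d_pre), floor_score = 0)
    }
    A_used[dom] <- A
    dtw100_log("%s domain: A = %g", dom, A)
    mk <- function(dists, subj, phase)
      new_score_card(subj$subject_id, dtw100_score(dists["lfp"], A),
                     dtw100_score(dists["emg"], A), cfg$composite_weight,
                     dom, phase, A)
    cards <- c(cards,
               Map(mk, d_pre, pre_prep, MoreArgs = list(phase = "pre")),
               Map(mk, d_post, post_prep, MoreArgs = list(phase = "post")))
  }

  scores <- if (length(cards)) score_table(cards) else
    data.frame(sample_id = character(), phase = character(),
               domain = character(), lfp_score = numeric(),
               emg_score = numeric(), composite = numeric(),
               coefficient_A = numeric(), stringsAsFactors = FALSE)

  comparisons <- list()
  for (dom in domains) {
    pre_c <- scores$composite[scores$domain == dom & scores$phase == "pre"]
    post_c <- scores$composite[scores$domain == dom & scores$phase == "post"]
    if (length(pre_c) >= 2 && length(pre_c) == length(post_c))
      comparisons[[dom]] <- paired_t_test(pre_c, post_c, domain = dom)
  }
  list(scores = scores,
       comparisons = if (length(comparisons)) comparison_table(comparisons)
                     else NULL,
       A = A_used, reference = ref, cards = cards)
}

#' Write a synthetic cohort to disk and return its manifest rows
#'
#' One delimited file per subject per modality plus manifest bookkeeping
#' (subject id, role, file paths, regime, seed).
#'
#' @param cohort list of subject pairs from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param role manifest role: `"reference"`, `"pre"`, or `"post"`.
#' @param spec the [cohort_spec()] used (recorded in the manifest).
#' @return A data.frame of manifest rows.
#' @export
write_cohort <- function(cohort, dir, role = c("reference", "pre", "post"),
                         spec = NULL) {
  role <- match.arg(role)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(cohort, function(pair) {
    sid <- pair$subject_id
    lfp_path <- file.path(dir, paste0(sid, "-lfp.csv"))
    emg_path <- file.path(dir, paste0(sid, "-emg.csv"))
    write_trials(pair$lfp, lfp_path)
    write_trials(pair$emg, emg_path)
    data.frame(subject_id = sid, role = role, lfp_path = lfp_path,
               emg_path = emg_path,
               regime = if (is.null(spec)) NA_character_ else spec$regime,
               seed = if (is.null(spec)) NA_integer_ else spec$seed,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

read_manifest_cohort <- function(manifest, role, rate) {
  rows <- manifest[manifest$role == role, , drop = FALSE]
  lapply(seq_len(nrow(rows)), function(i) {
    list(lfp = read_trials(rows$lfp_path[i], rate, "LFP",
                           label = rows$subject_id[i]),
         emg = read_trials(rows$emg_path[i], rate, "EMG",
                           label = rows$subject_id[i]),
         subject_id = rows$subject_id[i])
  })
}

#' Run the full pipeline from a manifest of trial files
#'
#' File-based front end to [score_cohorts()]: reads every cohort listed in
#' the manifest (columns `subject_id`, `role` in
#' reference/pre/post, `lfp_path`, `emg_path`), executes preprocessing,
#' reference construction, time- and frequency-domain scoring and the group
#' comparison, and optionally writes the score table, comparison table and a
#' plain-text report.
#'
#' @param manifest a data.frame or path to a delimited manifest file.
#' @param cfg a [run_config()].
#' @param out_dir if non-NULL, writes `scores.csv`, `comparisons.csv` and
#'   `report.txt` there.
#' @param domain `"both"`, `"time"`, or `"frequency"`.
#' @param bin_decimate spectral bin decimation (see [score_cohorts()]).
#' @return The [score_cohorts()] result, with an added `report` element
#'   (character vector of report lines).
#' @export
run_pipeline <- function(manifest, cfg = run_config(), out_dir = NULL,
                         domain = c("both", "time", "frequency"),
                         bin_decimate = 1L) {
  domain <- match.arg(domain)
  if (is.character(manifest)) {
    sep <- detect_sep(readLines(manifest, n = 1L))
    manifest <- read.table(manifest, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  }
  needed <- c("subject_id", "role", "lfp_path", "emg_path")
  if (!all(needed %in% names(manifest)))
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  bad_role <- setdiff(unique(manifest$role), c("reference", "pre", "post"))
  if (length(bad_role))
    stop("unknown manifest role(s): ", paste(bad_role, collapse = ", "))
  reference <- read_manifest_cohort(manifest, "reference", cfg$rate)
  pre <- read_manifest_cohort(manifest, "pre", cfg$rate)
  post <- read_manifest_cohort(manifest, "post", cfg$rate)
  if (length(reference) == 0L)
    stop("manifest lists no reference cohort")

  res <- score_cohorts(reference, pre, post, cfg, bin_decimate = bin_decimate,
                       domain = domain)
  res$report <- render_report(res, length(reference))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(res$scores, file.path(out_dir, "scores.csv"),
              row.names = FALSE)
    if (!is.null(res$comparisons))
      write.csv(res$comparisons, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
    writeLines(res$report, file.path(out_dir, "report.txt"))
  }
  res
}

render_report <- function(res, n_reference) {
  lines <- c("DTW-100 cortico-muscular coupling report",
             "========================================",
             sprintf("reference subjects: %d", n_reference),
             sprintf("scored subjects: %d score cards", nrow(res$scores)))
  if (nrow(res$scores) == 0L) {
    lines <- c(lines, "NOTICE: no pre/post subjects scored (reference only).")
    return(lines)
  }
  for (dom in unique(res$scores$domain)) {
    sub <- res$scores[res$scores$domain == dom, ]
    lines <- c(lines, "", sprintf("%s domain (A = %.6g):", dom,
                                  res$A[[dom]]))
    for (ph in unique(sub$phase)) {
      s <- sub[sub$phase == ph, ]
      if (nrow(s) >= 2) {
        m <- summarize_scores(s$composite)
        lines <- c(lines, sprintf("  %-4s composite %.1f +/- %.1f (n = %d)",
                                  ph, m["mean"], m["sd"], nrow(s)))
      }
    }
  }
  if (!is.null(res$comparisons)) {
    lines <- c(lines, "", "paired pre/post comparisons:")
    for (i in seq_len(nrow(res$comparisons))) {
      c_i <- res$comparisons[i, ]
      lines <- c(lines, sprintf(
        "  %-9s increase %.1f +/- %.1f, t(%d) = %.3f, p = %.3g",
        c_i$domain, c_i$mean_increase, c_i$sd_increase, c_i$n - 1,
        c_i$t_statistic, c_i$p_value))
    }
  } else {
    lines <- c(lines, "", "NOTICE: no paired pre/post cohort; no comparison.")
  }
  lines
}

#' Generate, score and compare the three synthetic study cohorts
#'
#' Convenience wrapper reproducing the full study design in one call: a
#' 30-subject normal reference cohort, nine ischemic subjects before
#' stimulation and the same nine after stimulation, scored in both domains.
#'
#' @param seed master seed; the three cohorts derive their seeds from it.
#' @param cfg a [run_config()].
#' @param n_reference,n_subjects cohort sizes (defaults 30 and 9).
#' @param n_trials trials per subject (default 30).
#' @param bin_decimate spectral bin decimation (see [score_cohorts()]).
#' @param domain `"both"`, `"time"`, or `"frequency"`.
#' @return As [score_cohorts()].
#' @examples
#' \donttest{
#' res <- run_synthetic_study(seed = 1, cfg = run_config(decimate = 8))
#' res$comparisons
#' }
#' @export
run_synthetic_study <- function(seed = 1L, cfg = run_config(),
                                n_reference = 30L, n_subjects = 9L,
                                n_trials = 30L, bin_decimate = 1L,
                                domain = c("both", "time", "frequency")) {
  domain <- match.arg(domain)
  seed <- as.integer(seed)
  reference <- generate_cohort(cohort_spec("normal", n_subjects = n_reference,
                                           n_trials = n_trials, seed = seed))
  pre <- generate_cohort(cohort_spec("bcao_pre", n_subjects = n_subjects,
                                     n_trials = n_trials, seed = seed + 1L))
  post <- generate_cohort(cohort_spec("bcao_post", n_subjects = n_subjects,
                                      n_trials = n_trials, seed = seed + 2L))
  score_cohorts(reference, pre, post, cfg, bin_decimate = bin_decimate,
                domain = domain)
}
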