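# End-to-end harnesses tying the modules together: per-segment feature /
# label extraction, the screening benchmark, and the biomarker-vs-density
# correlation study. These are what the worked examples and the
# reproduction script run.

#' Per-segment biomarker features and SAS reference labels
#'
#' For every record of a synthetic corpus of short segments: preprocess
#' (floor-clip + zero-phase low-pass), compute the optimal recurrence
#' threshold of the whole segment, detect desaturations against the
#' segment's known clean baseline level (a 5-min segment fully covered by
#' a desaturation train has no clean head from which a 3-min baseline
#' could be measured, so the reference label uses the generator's ground
#' truth level), read off the trailing-window desaturation count at the
#' segment end, and derive the SAS severity class.
#'
#' @param corpus a [generate_corpus()] result.
#' @param n_pct desaturation depth criterion in percentage points.
#' @param floor,cutoff preprocessing parameters.
#' @param l_min,n_grid biomarker parameters (see [eps_opt_segment()]).
#' @return data frame with columns `segment`, `eps_opt`, `degenerate`,
#'   `odd_count`, `sas_class`, `has_episode`.
#' @export
corpus_segment_features <- function(corpus, n_pct = 3, floor = 75,
                                    cutoff = 0.25, l_min = "auto",
                                    n_grid = 100) {
  rows <- lapply(seq_along(corpus), function(i) {
    rec <- corpus[[i]]$record
    truth <- corpus[[i]]$truth
    pre <- preprocess_oximetry(rec, floor = floor, cutoff = cutoff)
    e <- eps_opt_segment(pre, l_min = l_min, n_grid = n_grid)
    ev <- detect_desaturations(pre, baseline = truth$baseline_mean,
                               N = n_pct)
    t_end <- utils::tail(pre$times, 1) + 1 / pre$fs
    cnt <- odd_series(ev, t_grid = t_end)$count
    data.frame(segment = i, eps_opt = as.numeric(e),
               degenerate = isTRUE(attr(e, "degenerate")),
               odd_count = cnt,
               has_episode = any(truth$episode_mask))
  })
  out <- do.call(rbind, rows)
  out$sas_class <- sas_class_from_odd(out$odd_count)
  out
}

#' Synthetic SAS screening benchmark
#'
#' Generates a corpus of 5-min segments (half containing sawtooth
#' desaturation trains by default), derives per-segment biomarker values
#' and desaturation-based SAS labels, binarizes the labels under the
#' chosen scheme, and runs the classifier/ROC harness. This reproduces,
#' on fully synthetic data, the screening regime reported for clinical
#' recordings: AUC above 0.9 with sensitivity and specificity above 0.8.
#'
#' @param n_segments number of 5-min segments.
#' @param mix fraction of segments containing episodes.
#' @param scheme binarization scheme (see [binarize_sas()]).
#' @param algos classifiers to evaluate (see [evaluate_classifiers()]).
#' @param seed master seed for generation, split and fits.
#' @param fs sampling frequency of the segments in Hz.
#' @return list with `evaluation` (a `classifier_evaluation`), `features`
#'   (the per-segment table with labels), and `best`: list with `auc`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` of the best classifier.
#' @export
benchmark_sas_screening <- function(n_segments = 1200, mix = 0.5,
                                    scheme = ">Mild",
                                    algos = c("adaboost", "lda",
                                              "random_forest"),
                                    seed = 17, fs = 1) {
  template <- synthetic_config(duration_s = 300, fs = fs)
  corpus <- generate_corpus(n_segments, mix = mix, template = template,
                            seed = seed)
  feats <- corpus_segment_features(corpus)
  labels <- binarize_sas(feats$sas_class, scheme)
  ev <- evaluate_classifiers(matrix(feats$eps_opt, ncol = 1,
                                    dimnames = list(NULL, "eps_opt")),
                             labels, algos = algos,
                             seed = derive_seed(seed, 999983))
  b <- ev$results[[ev$best]]
  list(evaluation = ev, features = feats,
       best = list(algorithm = b$algorithm, auc = b$auc,
                   sensitivity = b$sensitivity,
                   specificity = b$specificity,
                   ppv = b$ppv, npv = b$npv))
}

#' Correlation between the rolling biomarker and the desaturation density
#'
#' Generates full-length synthetic sessions with several desaturation-train
#' episodes, computes the rolling 10-min optimal-threshold series and the
#' desaturation density on the same time grid (the window end times), and
#' reports the Pearson correlation between the two series over
#' episode-annotated periods, per session and averaged. The analysis
#' period for a session is the contiguous block from one window length
#' before the first annotated episode onset to one window length after
#' the last episode end:
#' the synthetic analog of a reported-sleep block, which contains the
#' event clusters, the quiet stretches between them, and the onset rise
#' and offset decay of both trailing-window metrics. (Clinically the
#' density is only interpretable during sleep; in the generator, episode
#' activity is what marks the sleep block.) Episodes start after the
#' first six minutes so the detector's own 3-min baseline head is clean.
#'
#' @param n_sessions number of sessions.
#' @param session_s session length in seconds (3 h default).
#' @param window_s,step_s rolling-window parameters in seconds.
#' @param n_pct desaturation depth criterion in percentage points.
#' @param n_episodes_range number of episodes per session (range).
#' @param episode_duration_range episode length range in seconds.
#' @param dilate_s margin around the episode block, in seconds; defaults
#'   to the window length.
#' @param seed master seed.
#' @param fs sampling frequency in Hz.
#' @return list with `per_session` (data frame: session, r, n_windows) and
#'   `mean_r`.
#' @export
epsopt_odd_correlation <- function(n_sessions = 10, session_s = 10800,
                                   window_s = 600, step_s = 60, n_pct = 3,
                                   n_episodes_range = c(3, 5),
                                   episode_duration_range = c(480, 900),
                                   dilate_s = NULL,
                                   seed = 1, fs = 1) {
  if (is.null(dilate_s)) dilate_s <- window_s
  template <- synthetic_config(duration_s = session_s, fs = fs)
  corpus <- generate_corpus(
    n_sessions, mix = 1, template = template,
    episode_opts = list(n_range = n_episodes_range,
                        duration_range = episode_duration_range,
                        min_start = 360, gap_s = 120),
    seed = seed)
  per <- lapply(seq_len(n_sessions), function(s) {
    rec <- corpus[[s]]$record
    truth <- corpus[[s]]$truth
    pre <- preprocess_oximetry(rec)
    es <- rolling_eps_opt(pre, window_s = window_s, step_s = step_s)
    ev <- detect_desaturations(pre, baseline = compute_baseline(pre),
                               N = n_pct)
    od <- odd_series(ev, t_grid = es$window_end_s, lookback_s = window_s)
    eps <- truth$config$episodes
    block <- c(min(eps$start_s) - dilate_s, max(eps$end_s) + dilate_s)
    overlaps <- es$window_end_s >= block[1] & es$window_end_s <= block[2]
    use <- overlaps & !es$degenerate
    r <- if (sum(use) >= 3 && stats::sd(es$eps_opt[use]) > 0 &&
             stats::sd(od$count[use]) > 0) {
      stats::cor(es$eps_opt[use], od$count[use])
    } else NA_real_
    data.frame(session = s, r = r, n_windows = sum(use))
  })
  per <- do.call(rbind, per)
  list(per_session = per, mean_r = mean(per$r, na.rm = TRUE))
}
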