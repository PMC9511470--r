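#' Rolling-window application of a scalar metric
#'
#' Slides a window of `window_s` seconds in steps of `step_s` seconds over
#' the record and evaluates `metric` on each window's values, turning the
#' record into a new time series of the metric. Windows are half-open
#' sample-index intervals of identical span; in addition to the regular
#' start lattice `0, S, 2S, ...`, a final window anchored to end exactly at
#' the end of the record is evaluated whenever the series length is not on
#' the lattice (and deduplicated when it is), so the tail of the recording
#' is always covered.
#'
#' @param record an [oximetry_record()].
#' @param window_s window length W in seconds.
#' @param step_s step S in seconds.
#' @param metric function taking a numeric vector (the window's values) and
#'   returning a scalar, optionally carrying a logical attribute
#'   `degenerate`.
#' @return a data frame of class `rolling_series` with columns
#'   `window_start_s`, `window_end_s`, `value`, `degenerate`, and
#'   attributes `window_s`, `step_s`.
#' @export
rolling_apply <- function(record, window_s, step_s, metric) {
  stopifnot(inherits(record, "oximetry_record"))
  fs <- record$fs
  n <- length(record$values)
  W <- as.integer(round(window_s * fs))
  S <- as.integer(round(step_s * fs))
  if (W < 2) stop("window too short (needs >= 2 samples)")
  if (S < 1) stop("'step_s' must be at least one sampling interval")
  if (W > n) stop("window (", window_s, " s) longer than the record")
  starts <- seq.int(0L, n - W, by = S)
  if (utils::tail(starts, 1) != n - W) starts <- c(starts, n - W)
  vals <- numeric(length(starts))
  flags <- logical(length(starts))
  for (j in seq_along(starts)) {
    seg <- record$values[(starts[j] + 1L):(starts[j] + W)]
    v <- metric(seg)
    vals[j] <- as.numeric(v)
    flags[j] <- isTRUE(attr(v, "degenerate"))
  }
  out <- data.frame(
    window_start_s = record$times[1] + starts / fs,
    window_end_s = record$times[1] + (starts + W) / fs,
    value = vals,
    degenerate = flags)
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  class(out) <- c("rolling_series", "data.frame")
  out
}

#' Rolling optimal recurrence threshold series
#'
#' The package's biomarker series: the optimal recurrence threshold of
#' every rolling window. 5-min windows with a 1-min step are used for
#' distribution/classification work; 10-min windows for comparison against
#' the desaturation density.
#'
#' @param record a preprocessed [oximetry_record()].
#' @param window_s window length in seconds (300 or 600 typical).
#' @param step_s step in seconds.
#' @param l_min minimal diagonal length in samples or `"auto"`
#'   ([l_min_for_fs()]).
#' @param n_grid threshold grid size per window.
#' @param theiler Theiler exclusion half-width.
#' @param smooth_w DET-curve smoothing window in grid points (see
#'   [epsilon_opt()]).
#' @return a data frame of class `eps_opt_series` with columns
#'   `window_start_s`, `window_end_s`, `eps_opt`, `degenerate`; degenerate
#'   windows (constant signal, no recurrence structure) are flagged, not
#'   dropped.
#' @export
rolling_eps_opt <- function(record, window_s = 300, step_s = 60,
                            l_min = "auto", n_grid = 100, theiler = 1,
                            smooth_w = 5) {
  if (identical(l_min, "auto")) l_min <- l_min_for_fs(record$fs)
  out <- rolling_apply(
    record, window_s, step_s,
    metric = function(v) {
      eps_opt_segment(v, fs = record$fs, l_min = l_min, n_grid = n_grid,
                      theiler = theiler, smooth_w = smooth_w)
    })
  names(out)[names(out) == "value"] <- "eps_opt"
  attr(out, "l_min") <- l_min
  class(out) <- c("eps_opt_series", class(out))
  out
}
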