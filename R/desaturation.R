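#' Baseline saturation of a record
#'
#' The reference level for desaturation detection: the arithmetic mean of
#' the first `minutes` of samples (3 min by default). The baseline is
#' computed once and held fixed for the whole record; no adaptive baseline
#' is used.
#'
#' @param record an [oximetry_record()].
#' @param minutes length of the head used for the average.
#' @return baseline SaO2 in percent.
#' @export
compute_baseline <- function(record, minutes = 3) {
  stopifnot(inherits(record, "oximetry_record"))
  k <- as.integer(round(minutes * 60 * record$fs))
  if (length(record$values) < k) {
    stop("record shorter than the ", minutes, "-min baseline head")
  }
  mean(record$values[seq_len(k)])
}

#' Detect oxygen desaturation events
#'
#' A desaturation is a maximal contiguous run of samples strictly below
#' `baseline - N` (N percentage points of SaO2, the conventional ODI3/ODI4
#' reading of "N%") that lasts at least `min_dur_s` and at most `max_dur_s`
#' seconds. Each event is timestamped at the instant the saturation first
#' falls below the threshold. Samples exactly at the threshold terminate a
#' run ("falls below" is strict). Durations are measured on the sample grid
#' as run length over `fs`; at 0.1 Hz the 10-s minimum is a single sample,
#' so low-rate detection is intrinsically coarse.
#'
#' @param record a preprocessed [oximetry_record()].
#' @param baseline reference level in percent; defaults to
#'   [compute_baseline()] on the record.
#' @param N desaturation depth criterion in percentage points (3 or 4
#'   conventional).
#' @param min_dur_s,max_dur_s admissible run duration bounds in seconds.
#' @return a data frame of class `desaturation_events` with columns
#'   `timestamp_s`, `start_s`, `end_s`, `depth_pct`, `duration_s`, ordered
#'   by timestamp. `end_s` is half-open (one sampling interval past the
#'   last sub-threshold sample), so `duration_s = end_s - start_s`.
#' @export
detect_desaturations <- function(record, baseline = NULL, N = 3,
                                 min_dur_s = 10, max_dur_s = 60) {
  stopifnot(inherits(record, "oximetry_record"))
  if (N <= 0) stop("'N' must be positive")
  if (is.null(baseline)) baseline <- compute_baseline(record)
  fs <- record$fs
  below <- record$values < baseline - N
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; lens <- r$lengths[keep]
  dur <- lens / fs
  ok <- dur >= min_dur_s & dur <= max_dur_s
  starts <- starts[ok]; lens <- lens[ok]; dur <- dur[ok]
  depth <- vapply(seq_along(starts), function(j) {
    baseline - min(record$values[starts[j]:(starts[j] + lens[j] - 1L)])
  }, numeric(1))
  out <- data.frame(
    timestamp_s = record$times[starts],
    start_s = record$times[starts],
    end_s = record$times[starts] + dur,
    depth_pct = depth,
    duration_s = dur)
  if (nrow(out) == 0) {
    out <- data.frame(timestamp_s = numeric(0), start_s = numeric(0),
                      end_s = numeric(0), depth_pct = numeric(0),
                      duration_s = numeric(0))
  }
  attr(out, "baseline") <- baseline
  attr(out, "N") <- N
  class(out) <- c("desaturation_events", "data.frame")
  out
}

#' Oxygen desaturation index (events per hour)
#'
#' Number of desaturation events per hour of reference time. With a sleep
#' annotation, only events whose timestamp falls inside a sleep interval
#' are counted and the reference duration is the total sleep time (the
#' conventional "per hour of sleep"); otherwise the whole-record duration
#' must be supplied.
#'
#' @param events a [detect_desaturations()] result.
#' @param sleep optional [sleep_annotation()].
#' @param duration_s whole-record reference duration in seconds (required
#'   when `sleep` is `NULL`).
#' @return events per hour.
#' @export
odi <- function(events, sleep = NULL, duration_s = NULL) {
  ts <- events$timestamp_s
  if (!is.null(sleep)) {
    ref_s <- sum(sleep$end_s - sleep$start_s)
    inside <- vapply(ts, function(t) {
      any(t >= sleep$start_s & t < sleep$end_s)
    }, logical(1))
    cnt <- sum(inside)
  } else {
    if (is.null(duration_s)) stop("need 'sleep' or 'duration_s'")
    ref_s <- duration_s
    cnt <- length(ts)
  }
  if (ref_s <= 0) stop("zero-duration reference period")
  cnt / (ref_s / 3600)
}

#' Oxygen desaturation density series
#'
#' For each time point `t` of the grid, the number of desaturation events
#' in the trailing `lookback_s` window, on the half-open interval
#' `(t - lookback_s, t]` (an event exactly at `t - lookback_s` is
#' excluded). The default 10-min window makes the density a time-resolved
#' companion to the hourly index.
#'
#' @param events a [detect_desaturations()] result.
#' @param t_grid increasing evaluation times in seconds (the rolling-window
#'   end times, typically, so that density and biomarker series align).
#' @param lookback_s trailing window length in seconds.
#' @return a data frame of class `odd_series` with columns `t_s`, `count`.
#' @export
odd_series <- function(events, t_grid, lookback_s = 600) {
  t_grid <- as.numeric(t_grid)
  if (length(t_grid) > 1 && any(diff(t_grid) <= 0)) {
    stop("'t_grid' must be increasing")
  }
  ts <- sort(events$timestamp_s)
  cnt <- findInterval(t_grid, ts) - findInterval(t_grid - lookback_s, ts)
  out <- data.frame(t_s = t_grid, count = as.integer(cnt))
  attr(out, "lookback_s") <- lookback_s
  class(out) <- c("odd_series", "data.frame")
  out
}
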