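#' Remove dropouts and sub-floor values by linear interpolation
#'
#' Oximeters emit dropout values (zeros, sentinels) and physiologically
#' implausible readings during probe artifacts. Every sample below `floor`
#' (75% SaO2 by default), as well as missing values, is removed and refilled
#' by linear interpolation between the nearest valid neighbours; runs of
#' invalid samples at either boundary are filled by nearest-valid constant
#' extension (no trend is invented beyond the data). Replaced samples are
#' marked `FALSE` in the validity mask.
#'
#' @param record an [oximetry_record()].
#' @param floor validity floor in percent SaO2.
#' @return a cleaned [oximetry_record()]. Errors if every sample is invalid.
#' @details The operation is idempotent: interpolated values lie between
#'   valid neighbours and therefore never fall below `floor` again.
#' @export
clip_and_interpolate <- function(record, floor = 75) {
  stopifnot(inherits(record, "oximetry_record"))
  v <- record$values
  bad <- is.na(v) | v < floor
  if (all(bad)) stop("unusable record: every sample below the ", floor,
                     "% floor")
  if (any(bad)) {
    idx <- seq_along(v)
    good <- which(!bad)
    if (length(good) == 1) {
      v[bad] <- v[good]
    } else {
      v[bad] <- stats::approx(x = good, y = v[good], xout = idx[bad],
                              rule = 2)$y
    }
  }
  oximetry_record(v, fs = record$fs, times = record$times,
                  valid_mask = record$valid_mask & !bad)
}

#' Zero-phase low-pass filter
#'
#' Applies a 4th-order Butterworth low-pass filter forward and backward
#' (zero phase, DC gain 1), so that desaturation event timing is preserved
#' for the downstream event timestamps. The series is extended by odd
#' reflection at both ends before filtering to suppress edge transients.
#'
#' @param record an [oximetry_record()].
#' @param cutoff cutoff frequency in Hz (default 0.25 Hz); must be below the
#'   Nyquist frequency `fs/2`.
#' @param order filter order (per pass).
#' @return the filtered [oximetry_record()] on the same grid.
#' @export
lowpass_filter <- function(record, cutoff = 0.25, order = 4) {
  stopifnot(inherits(record, "oximetry_record"))
  fs <- record$fs
  if (cutoff >= fs / 2) {
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency ",
         fs / 2, " Hz")
  }
  if (cutoff <= 0) stop("cutoff must be positive")
  x <- record$values
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # forward-backward pass over an odd-reflection extension; the pad must
  # out-last the IIR transient (repeated poles decay slowly)
  pad <- min(n - 1, max(100, ceiling(3 * fs / cutoff)))
  xext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y1 <- as.numeric(signal::filter(bf, xext))
  y <- rev(as.numeric(signal::filter(bf, rev(y1))))
  y <- y[(pad + 1):(pad + n)]
  oximetry_record(y, fs = fs, times = record$times,
                  valid_mask = record$valid_mask)
}

#' Resample by non-overlapping block averages
#'
#' Replaces every `block_s` seconds of signal by its arithmetic mean,
#' producing a series at `1/block_s` Hz (10-s blocks turn a 1 Hz series into
#' a 0.1 Hz one). A trailing partial block is dropped so the output length
#' is deterministic. Output time stamps are the block start times; a block
#' is marked valid only if all of its samples were.
#'
#' @param record an [oximetry_record()].
#' @param block_s block length in seconds; must be an integer multiple of
#'   the sampling interval.
#' @return the resampled [oximetry_record()] at `fs = 1/block_s`.
#' @export
resample_block_average <- function(record, block_s = 10) {
  stopifnot(inherits(record, "oximetry_record"))
  bn <- block_s * record$fs
  if (abs(bn - round(bn)) > 1e-9) {
    stop("'block_s' must be an integer multiple of the sampling interval")
  }
  bn <- as.integer(round(bn))
  if (bn < 1) stop("'block_s' shorter than one sample")
  n <- length(record$values)
  nb <- n %/% bn
  if (nb < 1) stop("record shorter than one block")
  keep <- seq_len(nb * bn)
  m <- matrix(record$values[keep], nrow = bn)
  vm <- matrix(record$valid_mask[keep], nrow = bn)
  oximetry_record(colMeans(m), fs = 1 / block_s,
                  start_s = record$times[1] +
                    (seq_len(nb) - 1) * block_s,
                  valid_mask = apply(vm, 2, all),
                  times = record$times[1] + (seq_len(nb) - 1) * block_s)
}

#' Full preprocessing chain
#'
#' Runs the standard chain floor-clip + interpolation, zero-phase low-pass
#' filtering at the original rate (which doubles as an anti-alias stage),
#' then optional block-average resampling.
#'
#' @param record raw [oximetry_record()].
#' @param floor validity floor in percent (see [clip_and_interpolate()]).
#' @param cutoff low-pass cutoff in Hz; `NULL` skips filtering.
#' @param block_s optional resampling block in seconds; `NULL` keeps the
#'   original rate.
#' @return the preprocessed [oximetry_record()].
#' @export
preprocess_oximetry <- function(record, floor = 75, cutoff = 0.25,
                                block_s = NULL) {
  rec <- clip_and_interpolate(record, floor = floor)
  if (!is.null(cutoff)) rec <- lowpass_filter(rec, cutoff = cutoff)
  if (!is.null(block_s)) rec <- resample_block_average(rec, block_s = block_s)
  rec
}
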