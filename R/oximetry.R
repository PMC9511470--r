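#' Construct an oximetry record
#'
#' An oximetry record is a uniformly sampled single-channel SaO2 series:
#' times in seconds on a strict grid, values in percent, the sampling
#' frequency `fs` in Hz, and a per-sample validity mask marking samples that
#' were measured (as opposed to interpolated/filled during preprocessing).
#'
#' @param values numeric vector of SaO2 values in percent.
#' @param fs sampling frequency in Hz (1.0 and 0.1 are the typical rates).
#' @param start_s time of the first sample in seconds.
#' @param valid_mask logical vector, `FALSE` where a sample was filled in.
#' @param times optional explicit time vector (seconds); must be a uniform
#'   grid consistent with `fs`.
#' @return an object of class `oximetry_record`: a list with elements
#'   `times`, `values`, `fs`, `valid_mask`.
#' @examples
#' rec <- oximetry_record(c(95, 94, 95, 96), fs = 1)
#' rec$times
#' @export
oximetry_record <- function(values, fs, start_s = 0,
                            valid_mask = rep(TRUE, length(values)),
                            times = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 1) stop("an oximetry record needs at least 1 sample")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("'fs' must be a single positive number (Hz)")
  }
  if (is.null(times)) {
    times <- start_s + (seq_len(n) - 1) / fs
  } else {
    times <- as.numeric(times)
    if (length(times) != n) stop("'times' and 'values' lengths differ")
    if (n > 1) {
      dt <- diff(times)
      if (any(dt <= 0)) stop("'times' must be strictly increasing")
      if (max(abs(dt - 1 / fs)) > 1e-8) {
        stop("'times' is not a uniform grid at the stated 'fs'")
      }
    }
  }
  if (length(valid_mask) != n || !is.logical(valid_mask)) {
    stop("'valid_mask' must be a logical vector matching 'values'")
  }
  structure(list(times = times, values = values, fs = fs,
                 valid_mask = valid_mask),
            class = "oximetry_record")
}

#' @export
print.oximetry_record <- function(x, ...) {
  cat(sprintf(
    "<oximetry_record> %d samples @ %g Hz, span %.1f s, SaO2 %.1f-%.1f%% (%d filled)\n",
    length(x$values), x$fs, utils::tail(x$times, 1) - x$times[1],
    min(x$values), max(x$values), sum(!x$valid_mask)))
  invisible(x)
}

#' @export
length.oximetry_record <- function(x) length(x$values)

span_s <- function(record) {
  utils::tail(record$times, 1) - record$times[1] + 1 / record$fs
}

#' Read an oximetry time series from delimited text
#'
#' Expects two columns (time in seconds, SaO2 in percent), comma-, tab- or
#' whitespace-separated, with an optional header line. The sampling
#' frequency is inferred from the median time step unless `fs_hint` is
#' given; time stamps are snapped to the exact uniform grid afterwards.
#'
#' @param path path to the file.
#' @param fs_hint optional sampling frequency in Hz, overriding inference.
#' @return an [oximetry_record()].
#' @details Reading fails on an empty file, non-numeric rows, non-monotone
#'   time stamps, or a grid whose step jitter exceeds 1% of the median step.
#' @export
read_oximetry <- function(path, fs_hint = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0) stop("empty oximetry file: ", path)
  sep <- if (grepl(",", raw[1])) "," else ""
  first <- strsplit(trimws(raw[1]), if (sep == ",") "," else "[ \t]+")[[1]]
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  dat <- utils::read.table(text = raw, sep = sep, header = header,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 2) stop("expected two columns (time_s, sao2_pct)")
  t_raw <- suppressWarnings(as.numeric(dat[[1]]))
  v_raw <- suppressWarnings(as.numeric(dat[[2]]))
  if (anyNA(t_raw) || anyNA(v_raw)) {
    stop("non-numeric rows in oximetry file: ", path)
  }
  if (length(t_raw) < 2) stop("oximetry file has fewer than 2 samples")
  dt <- diff(t_raw)
  if (any(dt <= 0)) stop("time stamps must be strictly increasing")
  step <- stats::median(dt)
  if (max(abs(dt - step)) > 0.01 * step) {
    stop("non-uniform sampling grid (jitter beyond 1% of the median step)")
  }
  fs <- if (is.null(fs_hint)) 1 / step else fs_hint
  oximetry_record(v_raw, fs = fs, start_s = t_raw[1])
}

#' Write an oximetry record as CSV
#'
#' @param record an [oximetry_record()].
#' @param path output path; columns `time_s`, `sao2_pct`.
#' @return `path`, invisibly.
#' @export
write_oximetry <- function(record, path) {
  stopifnot(inherits(record, "oximetry_record"))
  utils::write.table(
    data.frame(time_s = record$times, sao2_pct = record$values),
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sleep-interval annotations
#'
#' Sleep annotations restrict the reference metrics (ODI) to time the
#' subject was reported asleep. The file has columns `start_s`, `end_s` and
#' optionally `stage` (light/deep/unspecified).
#'
#' @param path CSV path.
#' @return a `sleep_annotation` data frame with columns `start_s`, `end_s`,
#'   `stage`, sorted and non-overlapping.
#' @export
read_sleep_annotation <- function(path) {
  dat <- utils::read.table(path, sep = ",", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s") %in% names(dat))) {
    stop("sleep annotation needs 'start_s' and 'end_s' columns")
  }
  if (is.null(dat$stage)) dat$stage <- "unspecified"
  sleep_annotation(dat$start_s, dat$end_s, dat$stage)
}

#' Construct sleep-interval annotations
#'
#' @param start_s,end_s interval bounds in seconds.
#' @param stage stage label per interval (`light`, `deep` or `unspecified`).
#' @return a `sleep_annotation` data frame.
#' @export
sleep_annotation <- function(start_s, end_s,
                             stage = rep("unspecified", length(start_s))) {
  start_s <- as.numeric(start_s); end_s <- as.numeric(end_s)
  if (any(end_s <= start_s)) stop("sleep intervals need start < end")
  ord <- order(start_s)
  start_s <- start_s[ord]; end_s <- end_s[ord]; stage <- stage[ord]
  if (length(start_s) > 1 &&
      any(start_s[-1] < end_s[-length(end_s)])) {
    stop("sleep intervals must not overlap")
  }
  structure(data.frame(start_s = start_s, end_s = end_s, stage = stage,
                       stringsAsFactors = FALSE),
            class = c("sleep_annotation", "data.frame"))
}
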