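#' Recurrence matrix of a scalar series
#'
#' Two samples are recurrent when their absolute difference is within the
#' threshold `epsilon`: `R[i, j] = 1` iff `|x_i - x_j| <= epsilon` (the
#' Heaviside step is taken right-continuous, so zero distance always
#' recurs). The series is used as-is, with no phase-space embedding: the
#' comparison is between raw signal values, which is the relevant notion of
#' similarity for saturation dynamics.
#'
#' @param x numeric vector, length >= 2.
#' @param epsilon recurrence threshold in signal units (percent SaO2 here);
#'   must be >= 0.
#' @return a binary integer matrix of class `recurrence_matrix` with
#'   attributes `epsilon` and `metric`; symmetric with unit main diagonal.
#' @examples
#' recurrence_matrix(c(0, 1, 0), 0.5)
#' @export
recurrence_matrix <- function(x, epsilon) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("'x' needs at least 2 samples")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon < 0) {
    stop("'epsilon' must be a single non-negative number")
  }
  R <- (abs(outer(x, x, "-")) <= epsilon) * 1L
  structure(R, epsilon = epsilon, metric = "absolute",
            class = c("recurrence_matrix", class(R)))
}

#' Histogram of diagonal line lengths in a recurrence matrix
#'
#' A diagonal line of length `l` arises when two distinct stretches of the
#' series stay within the threshold of each other for `l` consecutive
#' samples. Lines are maximal runs of ones along diagonals with offset
#' `|k| >= theiler`; the default Theiler window of 1 excludes only the line
#' of identity (which would otherwise contribute one artificial length-N
#' line to every histogram).
#'
#' @param R a [recurrence_matrix()] (any square binary matrix works).
#' @param theiler half-width of the excluded band around the main diagonal,
#'   in samples; `0 <= theiler < N`.
#' @return an object of class `diagonal_histogram`: a list with integer
#'   vectors `lengths` and `counts` (number of maximal lines of exactly
#'   each length) and the `theiler` value.
#' @export
diagonal_histogram <- function(R, theiler = 1) {
  n <- nrow(R)
  if (is.null(n) || n != ncol(R)) stop("'R' must be a square matrix")
  if (theiler < 0 || theiler >= n) stop("need 0 <= theiler < N")
  tab <- integer(n)
  for (k in seq(-(n - 1), n - 1)) {
    if (abs(k) < theiler) next
    i <- seq_len(n - abs(k))
    d <- if (k >= 0) R[cbind(i, i + k)] else R[cbind(i + abs(k), i)]
    r <- rle(as.integer(d) != 0L)
    lens <- r$lengths[r$values]
    for (l in lens) tab[l] <- tab[l] + 1L
  }
  keep <- which(tab > 0L)
  structure(list(lengths = keep, counts = tab[keep],
                 theiler = as.integer(theiler)),
            class = "diagonal_histogram")
}

#' @export
print.diagonal_histogram <- function(x, ...) {
  cat("<diagonal_histogram> theiler =", x$theiler, "\n")
  if (length(x$lengths)) {
    print(stats::setNames(x$counts, x$lengths))
  } else cat("(empty)\n")
  invisible(x)
}

#' Determinism of a recurrence plot
#'
#' DET is the fraction of recurrent points lying on diagonal lines of
#' length at least `l_min`:
#' `DET = sum_{l >= l_min} l P(l) / sum_{l >= 1} l P(l)`.
#' Periodic signals have DET near 1, uncorrelated noise near 0. When the
#' histogram is empty (no off-Theiler recurrences at all) the value is the
#' sentinel 0 with attribute `degenerate = TRUE`, so such segments can be
#' excluded downstream rather than silently scored.
#'
#' @param hist a [diagonal_histogram()].
#' @param l_min minimal diagonal length counted, in samples (>= 1).
#' @return DET in `[0, 1]` with logical attribute `degenerate`.
#' @export
determinism <- function(hist, l_min) {
  stopifnot(inherits(hist, "diagonal_histogram"))
  if (l_min < 1) stop("'l_min' must be >= 1")
  den <- sum(hist$lengths * hist$counts)
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  sel <- hist$lengths >= l_min
  num <- sum(hist$lengths[sel] * hist$counts[sel])
  structure(num / den, degenerate = FALSE)
}

#' Default threshold grid for a segment
#'
#' 100 uniformly spaced thresholds starting at 0, spanning the segment's
#' maximum pairwise distance (its range), with a minimum spacing guard of
#' 0.01 signal units so near-constant segments still get a usable grid.
#'
#' @param x numeric segment.
#' @param n number of grid points.
#' @param min_spacing smallest allowed spacing in signal units.
#' @return strictly increasing numeric vector of length `n`.
#' @export
default_eps_grid <- function(x, n = 100, min_spacing = 0.01) {
  if (n < 3) stop("grid needs at least 3 points")
  maxd <- diff(range(x))
  spacing <- max(maxd / (n - 1), min_spacing)
  seq(0, by = spacing, length.out = n)
}

#' Default minimal diagonal length for a sampling rate
#'
#' The counted diagonal lines should span roughly 10 s of signal: 10
#' samples at 1 Hz, 2 samples at 0.1 Hz (never fewer than 2).
#'
#' @param fs sampling frequency in Hz.
#' @return integer `l_min` in samples.
#' @export
l_min_for_fs <- function(fs) {
  max(2L, as.integer(round(10 * fs)))
}

#' DET as a function of the recurrence threshold
#'
#' Evaluates `determinism(diagonal_histogram(recurrence_matrix(x, eps)))`
#' over a grid of thresholds. The computation runs in compiled code (one
#' pass over the pairwise distances per grid point); the result is
#' identical to composing the three R-level operations.
#'
#' @param x numeric segment, length >= 2.
#' @param eps_grid strictly increasing thresholds (>= 3 points); defaults
#'   to [default_eps_grid()].
#' @param l_min minimal diagonal length in samples.
#' @param theiler Theiler exclusion half-width in samples.
#' @return an object of class `det_curve`: list with `eps`, `det`,
#'   `recurrences` (off-Theiler recurrent point count per threshold, the
#'   DET denominator), `l_min`, `theiler`.
#' @export
det_curve <- function(x, eps_grid = NULL, l_min, theiler = 1) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("'x' needs at least 2 samples")
  if (is.null(eps_grid)) eps_grid <- default_eps_grid(x)
  if (length(eps_grid) < 3 || any(diff(eps_grid) <= 0)) {
    stop("'eps_grid' must be strictly increasing with >= 3 points")
  }
  if (l_min < 1) stop("'l_min' must be >= 1")
  res <- rqa_det_curve_cpp(x, eps_grid, as.integer(l_min),
                           as.integer(theiler))
  structure(list(eps = eps_grid, det = res$det,
                 recurrences = res$recurrences,
                 l_min = as.integer(l_min), theiler = as.integer(theiler)),
            class = "det_curve")
}

#' @export
print.det_curve <- function(x, ...) {
  cat(sprintf("<det_curve> %d thresholds in [%g, %g], l_min = %d\n",
              length(x$eps), min(x$eps), max(x$eps), x$l_min))
  invisible(x)
}

#' Optimal recurrence threshold of a segment
#'
#' The optimal threshold is the grid point at which DET rises fastest:
#' `argmax dDET/deps`, with the derivative estimated by central finite
#' differences in the grid interior and one-sided differences at the ends.
#' Ties are broken toward the smallest threshold (a single unit step in DET
#' between adjacent grid points therefore reports the lower of the two).
#' Small thresholds suffice for ordered, quasi-constant saturation; large
#' excursion trains push the fastest DET rise to larger thresholds, which
#' is what makes this an intermittency biomarker.
#'
#' @param curve a [det_curve()].
#' @param smooth_w odd moving-average window (in grid points) applied to
#'   the DET curve before differentiation; 1 (the default here) uses the
#'   raw curve. The empirical DET curve is stepwise constant, so the raw
#'   adjacent-step derivative is dominated by the granularity of the
#'   pairwise-distance distribution; the segment-level wrappers
#'   ([eps_opt_segment()], [rolling_eps_opt()]) therefore default to a
#'   light smoothing (window 5, about 5% of the grid span), which
#'   stabilizes the argmax without displacing the rise region. Near the
#'   grid edges the window shrinks symmetrically.
#' @return the optimal threshold in signal units, with logical attribute
#'   `degenerate`: `TRUE` when the DET curve is flat (constant segment, or
#'   no recurrence structure at any threshold), in which case the smallest
#'   grid value is returned and the segment should be excluded from
#'   downstream distributions.
#' @export
epsilon_opt <- function(curve, smooth_w = 1) {
  stopifnot(inherits(curve, "det_curve"))
  eps <- curve$eps
  det <- curve$det
  g <- length(eps)
  if (smooth_w > 1) {
    h <- floor(smooth_w / 2)
    det <- vapply(seq_len(g), function(i) {
      k <- min(h, i - 1, g - i)    # symmetric shrink at the edges
      mean(det[(i - k):(i + k)])
    }, numeric(1))
  }
  d <- numeric(g)
  d[1] <- (det[2] - det[1]) / (eps[2] - eps[1])
  d[g] <- (det[g] - det[g - 1]) / (eps[g] - eps[g - 1])
  if (g > 2) {
    i <- 2:(g - 1)
    d[i] <- (det[i + 1] - det[i - 1]) / (eps[i + 1] - eps[i - 1])
  }
  if (diff(range(d)) < 1e-12) {
    return(structure(eps[1], degenerate = TRUE))
  }
  structure(eps[which.max(d)], degenerate = FALSE)
}

#' Optimal recurrence threshold straight from a segment
#'
#' Convenience wrapper: builds the default grid, evaluates the DET curve
#' and locates the threshold of fastest DET rise.
#'
#' @param x numeric segment or an [oximetry_record()].
#' @param fs sampling frequency in Hz (ignored when `x` is a record);
#'   needed only to resolve `l_min = "auto"`.
#' @param l_min minimal diagonal length in samples, or `"auto"` to use
#'   [l_min_for_fs()].
#' @param n_grid number of threshold grid points.
#' @param theiler Theiler exclusion half-width.
#' @param smooth_w DET-curve smoothing window in grid points (see
#'   [epsilon_opt()]); the biomarker default is 5.
#' @return optimal threshold with attribute `degenerate` (see
#'   [epsilon_opt()]).
#' @export
eps_opt_segment <- function(x, fs = NULL, l_min = "auto", n_grid = 100,
                            theiler = 1, smooth_w = 5) {
  if (inherits(x, "oximetry_record")) {
    fs <- x$fs
    x <- x$values
  }
  if (identical(l_min, "auto")) {
    if (is.null(fs)) stop("'fs' needed to resolve l_min = \"auto\"")
    l_min <- l_min_for_fs(fs)
  }
  epsilon_opt(det_curve(x, default_eps_grid(x, n = n_grid),
                        l_min = l_min, theiler = theiler),
              smooth_w = smooth_w)
}
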