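# Independent brute-force oracles and small fixture builders.

# Diagonal-line histogram by explicit element-wise scanning of every
# diagonal of the recurrence structure of x at threshold eps. Returns a
# named integer vector: names are line lengths, values are counts.
oracle_diag_hist <- function(x, eps, theiler = 1) {
  n <- length(x)
  counts <- integer(0)
  bump <- function(counts, l) {
    key <- as.character(l)
    if (is.null(counts[key]) || is.na(counts[key])) counts[key] <- 0L
    counts[key] <- counts[key] + 1L
    counts
  }
  for (k in seq(-(n - 1), n - 1)) {
    if (abs(k) < theiler) next
    run <- 0L
    for (i in seq_len(n)) {
      j <- i + k
      rec <- j >= 1 && j <= n && abs(x[i] - x[j]) <= eps
      if (rec) {
        run <- run + 1L
      } else if (run > 0L) {
        counts <- bump(counts, run)
        run <- 0L
      }
    }
    if (run > 0L) counts <- bump(counts, run)
  }
  if (length(counts) == 0) return(stats::setNames(integer(0), character(0)))
  counts[order(as.integer(names(counts)))]
}

# DET straight from an oracle histogram.
oracle_det <- function(hist_named, l_min) {
  if (length(hist_named) == 0) return(0)
  l <- as.integer(names(hist_named))
  den <- sum(l * hist_named)
  num <- sum((l * hist_named)[l >= l_min])
  num / den
}

# Convert the package's diagonal_histogram to the oracle's named form.
hist_as_named <- function(h) {
  out <- as.integer(h$counts)
  names(out) <- as.character(h$lengths)
  out
}

# Exhaustive 1-D natural-breaks search: all placements of k-1 breaks over
# the sorted values; returns minimal within-class SSE.
oracle_jenks_ss <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  best <- Inf
  combs <- utils::combn(n - 1, k - 1)
  for (c in seq_len(ncol(combs))) {
    cuts <- c(0, combs[, c], n)
    tot <- 0
    for (j in seq_len(k)) tot <- tot + sse(x[(cuts[j] + 1):cuts[j + 1]])
    if (tot < best) best <- tot
  }
  best
}

# All base-3 sequences of a given length, as rows of a matrix.
all_ternary <- function(len) {
  grid <- do.call(expand.grid, rep(list(0:2), len))
  as.matrix(grid)
}

constant_record <- function(value = 95, n = 120, fs = 1) {
  oximetry_record(rep(value, n), fs = fs)
}
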