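#' IHHOP class thresholds
#'
#' The two boundaries that split the biomarker range into "no IHHOP",
#' "maybe IHHOP" and "with IHHOP". The defaults (0.33 and 0.73, in percent
#' SaO2 for 1 Hz / l_min = 10 analysis of 5-min segments) come from
#' natural-breaks classing of a clinical distribution and should be
#' re-derived with [jenks_breaks()] for corpora with different segment
#' lengths, sampling rates or `l_min`.
#'
#' @param t_low,t_high class boundaries in signal units, `0 < t_low <
#'   t_high`.
#' @return an object of class `ihhop_thresholds`.
#' @export
ihhop_thresholds <- function(t_low = 0.33, t_high = 0.73) {
  if (!(t_low > 0 && t_high > t_low)) stop("need 0 < t_low < t_high")
  structure(list(t_low = t_low, t_high = t_high),
            class = "ihhop_thresholds")
}

#' @export
print.ihhop_thresholds <- function(x, ...) {
  cat(sprintf("<ihhop_thresholds> no < %g <= maybe < %g <= with\n",
              x$t_low, x$t_high))
  invisible(x)
}

#' Jenks natural breaks (exact 1-D classing)
#'
#' Splits sorted scalar values into `k` classes minimizing the total
#' within-class sum of squared deviations, by exact dynamic programming
#' (every contiguous partition is considered). Interior breaks are reported
#' as the midpoint between the last value of one class and the first value
#' of the next. Exact up to n = 10,000; larger inputs are refused (sample
#' them down first).
#'
#' @param values numeric vector with at least `k` distinct values.
#' @param k number of classes.
#' @return numeric vector of `k - 1` increasing break points, with
#'   attributes `within_ss` (the minimized criterion) and `k`.
#' @export
jenks_breaks <- function(values, k = 3) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (k < 1) stop("'k' must be >= 1")
  if (length(unique(x)) < k) stop("need at least ", k, " distinct values")
  if (n > 10000) {
    stop("exact natural breaks limited to n <= 10000; subsample first")
  }
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  sse_to <- function(i, j) {
    # within-class SSE of x[i..j], vectorized over i
    s <- cs[j] - c(0, cs)[i]
    s2 <- cs2[j] - c(0, cs2)[i]
    pmax(s2 - s^2 / (j - i + 1), 0)
  }
  if (k == 1) {
    out <- numeric(0)
    attr(out, "within_ss") <- sse_to(1, n)
    attr(out, "k") <- 1L
    return(out)
  }
  D <- sse_to(1, seq_len(n))        # best cost, 1 class, prefix i
  split <- matrix(0L, nrow = n, ncol = k)
  for (cls in 2:k) {
    Dnew <- rep(Inf, n)
    for (i in cls:n) {
      m <- cls:i                     # first index of the last class
      cost <- D[m - 1] + sse_to(m, i)
      j <- which.min(cost)
      Dnew[i] <- cost[j]
      split[i, cls] <- m[j]
    }
    D <- Dnew
  }
  # backtrack class boundaries
  bounds <- integer(k - 1)
  i <- n
  for (cls in k:2) {
    first <- split[i, cls]
    bounds[cls - 1] <- first       # index of the first value in class cls
    i <- first - 1L
  }
  breaks <- (x[bounds - 1L] + x[bounds]) / 2
  attr(breaks, "within_ss") <- D[n]
  attr(breaks, "k") <- as.integer(k)
  breaks
}

#' Derive IHHOP thresholds from a biomarker corpus
#'
#' Three-class natural breaks over a corpus of per-segment optimal
#' recurrence thresholds, wrapped as [ihhop_thresholds()].
#'
#' @param eps_values per-segment biomarker values (degenerate segments
#'   should be excluded beforehand).
#' @return an [ihhop_thresholds()].
#' @export
ihhop_thresholds_from_corpus <- function(eps_values) {
  b <- jenks_breaks(eps_values, k = 3)
  ihhop_thresholds(t_low = b[1], t_high = b[2])
}

#' Classify segments into IHHOP classes
#'
#' @param eps_opt per-segment biomarker values (vectorized).
#' @param thr an [ihhop_thresholds()].
#' @return factor with levels `no < maybe < with`: `no` below `t_low`,
#'   `maybe` in `[t_low, t_high)`, `with` at or above `t_high`.
#' @export
classify_ihhop <- function(eps_opt, thr = ihhop_thresholds()) {
  stopifnot(inherits(thr, "ihhop_thresholds"))
  if (any(eps_opt < 0)) stop("'eps_opt' must be non-negative")
  cls <- ifelse(eps_opt < thr$t_low, "no",
                ifelse(eps_opt < thr$t_high, "maybe", "with"))
  factor(cls, levels = c("no", "maybe", "with"), ordered = TRUE)
}

#' SAS severity class from a 10-min desaturation count
#'
#' Converts the trailing-10-min desaturation count to an hourly event rate
#' (factor 6) and applies the ASDS apnea-hypopnea severity cut-offs: mild
#' 5-15, moderate 15-30, severe above 30 events per hour; boundary rates
#' are assigned to the higher class.
#'
#' @param odd_count desaturation count(s) per trailing 10 min (vectorized).
#' @return factor with levels `healthy < mild < moderate < severe`.
#' @export
sas_class_from_odd <- function(odd_count) {
  if (any(odd_count < 0)) stop("'odd_count' must be non-negative")
  rate <- odd_count * 6
  cls <- ifelse(rate >= 30, "severe",
                ifelse(rate >= 15, "moderate",
                       ifelse(rate >= 5, "mild", "healthy")))
  factor(cls, levels = c("healthy", "mild", "moderate", "severe"),
         ordered = TRUE)
}

#' Binarize SAS severity for screening
#'
#' Three schemes: `">Mild"` marks mild, moderate and severe as positive
#' (`with_sas`); `">Moderate"` marks moderate and severe; `">Severe"`
#' marks only severe. The positive sets are nested accordingly.
#'
#' @param sas_class factor from [sas_class_from_odd()].
#' @param scheme one of `">Mild"`, `">Moderate"`, `">Severe"` (case
#'   insensitive, leading `>` optional).
#' @return factor with levels `without_sas`, `with_sas`.
#' @export
binarize_sas <- function(sas_class, scheme = ">Mild") {
  key <- tolower(sub("^>", "", scheme))
  lvl <- switch(key,
                mild = "mild", moderate = "moderate", severe = "severe",
                stop("unknown scheme: ", scheme))
  pos <- as.integer(sas_class) >=
    match(lvl, c("healthy", "mild", "moderate", "severe"))
  factor(ifelse(pos, "with_sas", "without_sas"),
         levels = c("without_sas", "with_sas"))
}

confusion_metrics <- function(tp, fp, tn, fn) {
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Evaluate binary SAS classifiers on biomarker features
#'
#' Screening harness: z-score normalization fitted on the training split
#' only, a 70/30 stratified train/test split, three classifiers (discrete
#' AdaBoost over decision stumps, linear discriminant analysis, random
#' forest), test-set ROC/AUC, and an operating point chosen as the ROC
#' point farthest (Euclidean) from the worst corner (FPR = 1, TPR = 0),
#' where sensitivity, specificity, PPV and NPV are reported. Segments are
#' treated as independent, so segments from the same recording may land in
#' both splits.
#'
#' @param features numeric matrix or data frame of per-segment features
#'   (typically the single biomarker column).
#' @param labels factor with levels `without_sas`, `with_sas` (or any
#'   2-level factor; the second level is the positive class).
#' @param algos subset of `c("adaboost", "lda", "random_forest")`.
#' @param train_frac training fraction of the stratified split.
#' @param seed integer seed making split and classifier fits reproducible.
#' @return an object of class `classifier_evaluation`: list with `results`
#'   (one entry per algorithm: `auc`, `roc` (fpr/tpr/thresholds),
#'   `operating_point`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   confusion counts) and `best` (algorithm name with the largest AUC).
#' @export
evaluate_classifiers <- function(features, labels,
                                 algos = c("adaboost", "lda",
                                           "random_forest"),
                                 train_frac = 0.7, seed = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  }
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("'labels' must have exactly two classes")
  if (nrow(features) != length(labels)) stop("feature/label length mismatch")
  if (nrow(features) < 20) stop("need at least 20 segments")
  if (any(apply(features, 2, stats::sd) == 0)) {
    stop("degenerate feature with zero variance")
  }
  algos <- match.arg(algos, several.ok = TRUE)
  pos <- levels(labels)[2]
  neg <- levels(labels)[1]

  run <- function() {
    idx_tr <- unlist(lapply(levels(labels), function(l) {
      w <- which(labels == l)
      sample(w, size = round(train_frac * length(w)))
    }))
    idx_te <- setdiff(seq_along(labels), idx_tr)
    mu <- colMeans(features[idx_tr, , drop = FALSE])
    sg <- apply(features[idx_tr, , drop = FALSE], 2, stats::sd)
    sg[sg == 0] <- 1
    z <- sweep(sweep(features, 2, mu), 2, sg, "/")
    ztr <- z[idx_tr, , drop = FALSE]
    zte <- z[idx_te, , drop = FALSE]
    ytr <- labels[idx_tr]
    yte <- labels[idx_te]

    score_fns <- list(
      lda = function() {
        fit <- MASS::lda(ztr, grouping = ytr)
        predict(fit, zte)$posterior[, pos]
      },
      random_forest = function() {
        fit <- randomForest::randomForest(ztr, y = ytr, ntree = 500)
        predict(fit, zte, type = "prob")[, pos]
      },
      adaboost = function() {
        fit <- adaboost_fit(ztr, ytr, positive = pos)
        adaboost_score(fit, zte)
      })

    results <- lapply(algos, function(a) {
      score <- score_fns[[a]]()
      r <- pROC::roc(response = yte, predictor = score,
                     levels = c(neg, pos), direction = "<", quiet = TRUE)
      fpr <- 1 - r$specificities
      tpr <- r$sensitivities
      dist <- sqrt((fpr - 1)^2 + tpr^2)
      i <- which.max(dist)
      n_pos <- sum(yte == pos)
      n_neg <- sum(yte == neg)
      tp <- round(tpr[i] * n_pos)
      fn <- n_pos - tp
      fp <- round(fpr[i] * n_neg)
      tn <- n_neg - fp
      cm <- confusion_metrics(tp, fp, tn, fn)
      c(list(algorithm = a,
             auc = as.numeric(pROC::auc(r)),
             roc = data.frame(threshold = r$thresholds, fpr = fpr,
                              tpr = tpr),
             operating_point = list(threshold = r$thresholds[i],
                                    tpr = tpr[i], fpr = fpr[i]),
             confusion = list(tp = tp, fp = fp, tn = tn, fn = fn)),
        cm)
    })
    names(results) <- algos
    results
  }

  results <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  aucs <- vapply(results, function(r) r$auc, numeric(1))
  structure(list(results = results, best = names(which.max(aucs)),
                 positive = pos, train_frac = train_frac, seed = seed),
            class = "classifier_evaluation")
}

#' @export
print.classifier_evaluation <- function(x, ...) {
  cat("<classifier_evaluation> positive class:", x$positive, "\n")
  for (r in x$results) {
    cat(sprintf(
      "  %-13s AUC %.3f  sens %.3f  spec %.3f  PPV %.3f  NPV %.3f\n",
      r$algorithm, r$auc, r$sensitivity, r$specificity, r$ppv, r$npv))
  }
  cat("  best by AUC:", x$best, "\n")
  invisible(x)
}
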