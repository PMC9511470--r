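# Discrete AdaBoost.M1 over rpart decision stumps. Scores are real-valued
# margins (sum of alpha-weighted stump votes), suitable for ROC analysis.

#' Fit a discrete AdaBoost stump ensemble
#'
#' Classic AdaBoost.M1 with depth-1 CART stumps as weak learners and
#' exponential-loss round weights. Training stops early when a stump is
#' perfect or no better than chance on the weighted sample.
#'
#' @param x numeric matrix or data frame of features.
#' @param y 2-level factor; the positive class is `positive`.
#' @param positive label of the positive class (default: second level).
#' @param n_rounds maximum number of boosting rounds.
#' @return an object of class `adaboost` (list of stumps and weights).
#' @export
adaboost_fit <- function(x, y, positive = NULL, n_rounds = 50) {
  x <- as.data.frame(x)
  y <- factor(y)
  if (nlevels(y) != 2) stop("adaboost needs a 2-level factor response")
  if (is.null(positive)) positive <- levels(y)[2]
  sign_y <- ifelse(y == positive, 1, -1)
  n <- length(y)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0)
  dat <- cbind(x, .y = y)
  for (t in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dat, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, x, type = "class")
    sign_p <- ifelse(pred == positive, 1, -1)
    err <- sum(w[sign_p != sign_y])
    if (err >= 0.5) {
      if (length(stumps) == 0) {   # keep one stump even if uninformative
        stumps[[1]] <- fit
        alphas <- 1e-3
      }
      break
    }
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
    w <- w * exp(-alpha * sign_y * sign_p)
    w <- w / sum(w)
  }
  structure(list(stumps = stumps, alphas = alphas, positive = positive,
                 levels = levels(y)),
            class = "adaboost")
}

#' Real-valued AdaBoost score
#'
#' @param fit an [adaboost_fit()] model.
#' @param newdata feature matrix or data frame.
#' @return numeric margin per row; larger means more positive-class.
#' @export
adaboost_score <- function(fit, newdata) {
  stopifnot(inherits(fit, "adaboost"))
  newdata <- as.data.frame(newdata)
  s <- numeric(nrow(newdata))
  for (t in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[t]], newdata, type = "class")
    s <- s + fit$alphas[t] * ifelse(pred == fit$positive, 1, -1)
  }
  s / sum(fit$alphas)
}

#' @export
predict.adaboost <- function(object, newdata, ...) {
  s <- adaboost_score(object, newdata)
  neg <- setdiff(object$levels, object$positive)
  factor(ifelse(s >= 0, object$positive, neg), levels = object$levels)
}
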