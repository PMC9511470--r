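test_that("jenks_breaks separates perfectly clustered values", {
  v <- c(1, 1, 1, 5, 5, 5, 10, 10, 10)
  b <- jenks_breaks(v, k = 3)
  expect_length(b, 2)
  expect_gt(b[1], 1); expect_lt(b[1], 5)
  expect_gt(b[2], 5); expect_lt(b[2], 10)
  expect_equal(attr(b, "within_ss"), 0)

  b1 <- jenks_breaks(v, k = 1)
  expect_length(b1, 0)
  expect_equal(attr(b1, "within_ss"), sum((v - mean(v))^2))

  expect_error(jenks_breaks(c(1, 1, 2, 2), k = 3), "distinct")
})

test_that("jenks_breaks matches exhaustive partition search", {
  withr::with_seed(47, {
    for (i in 1:6) {
      n <- sample(10:60, 1)
      k <- sample(2:4, 1)
      v <- round(runif(n, 0, 10), 2)
      if (length(unique(v)) < k) next
      b <- jenks_breaks(v, k)
      expect_equal(attr(b, "within_ss"), oracle_jenks_ss(v, k),
                   tolerance = 1e-10)
    }
  })
})

test_that("jenks_breaks recovers three-component mixture boundaries", {
  withr::with_seed(53, {
    v <- c(rnorm(70, 0.2, 0.03), rnorm(70, 0.5, 0.03), rnorm(60, 0.9, 0.03))
    b <- jenks_breaks(v, k = 3)
    expect_lt(abs(b[1] - 0.35), 0.05)
    expect_lt(abs(b[2] - 0.70), 0.05)
    thr <- ihhop_thresholds_from_corpus(v)
    expect_s3_class(thr, "ihhop_thresholds")
    expect_equal(thr$t_low, b[1])
  })
})

test_that("classify_ihhop applies the printed default boundaries", {
  expect_equal(as.character(classify_ihhop(c(0.10, 0.50, 0.90))),
               c("no", "maybe", "with"))
  # boundaries belong to the upper class
  expect_equal(as.character(classify_ihhop(c(0.33, 0.73))),
               c("maybe", "with"))
})

test_that("classify_ihhop is monotone in the biomarker", {
  withr::with_seed(59, {
    thr <- ihhop_thresholds(0.4, 0.8)
    v <- sort(runif(50, 0, 1.5))
    cls <- classify_ihhop(v, thr)
    expect_true(all(diff(as.integer(cls)) >= 0))
  })
})

test_that("sas_class_from_odd converts 10-min counts to hourly classes", {
  expect_equal(as.character(sas_class_from_odd(0)), "healthy")
  expect_equal(as.character(sas_class_from_odd(1)), "mild")    # 6 /h
  expect_equal(as.character(sas_class_from_odd(3)), "moderate") # 18 /h
  expect_equal(as.character(sas_class_from_odd(6)), "severe")  # 36 /h
  expect_equal(as.character(sas_class_from_odd(5)), "severe")  # 30 /h -> higher
})

test_that("binarize_sas follows the three schemes and nests positives", {
  cls <- sas_class_from_odd(c(0, 1, 3, 6))
  expect_equal(as.character(binarize_sas(cls, ">Mild")),
               c("without_sas", "with_sas", "with_sas", "with_sas"))
  expect_equal(as.character(binarize_sas(cls, ">Moderate")),
               c("without_sas", "without_sas", "with_sas", "with_sas"))
  expect_equal(as.character(binarize_sas(cls, ">Severe")),
               c("without_sas", "without_sas", "without_sas", "with_sas"))

  withr::with_seed(61, {
    cls2 <- sas_class_from_odd(sample(0:7, 100, replace = TRUE))
    p_mild <- binarize_sas(cls2, ">Mild") == "with_sas"
    p_mod <- binarize_sas(cls2, ">Moderate") == "with_sas"
    p_sev <- binarize_sas(cls2, ">Severe") == "with_sas"
    expect_true(all(p_sev <= p_mod))
    expect_true(all(p_mod <= p_mild))
  })
})

test_that("confusion metrics follow their closed forms", {
  m <- ihhop:::confusion_metrics(tp = 9, fp = 2, tn = 8, fn = 1)
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$ppv, 9 / 11)
  expect_equal(m$npv, 8 / 9)
})

test_that("PPV falls with prevalence at fixed sensitivity/specificity", {
  sens <- 0.9; spec <- 0.85
  ppv <- vapply(c(0.5, 0.3, 0.1, 0.05), function(prev) {
    n <- 10000
    tp <- sens * prev * n; fn <- (1 - sens) * prev * n
    tn <- spec * (1 - prev) * n; fp <- (1 - spec) * (1 - prev) * n
    ihhop:::confusion_metrics(tp, fp, tn, fn)$ppv
  }, numeric(1))
  expect_true(all(diff(ppv) < 0))
})

test_that("evaluate_classifiers is exact on a separable feature", {
  withr::with_seed(67, {
    n <- 60
    lab <- factor(rep(c("without_sas", "with_sas"), each = n / 2),
                  levels = c("without_sas", "with_sas"))
    x <- ifelse(lab == "with_sas", 1.0, 0.1) + rnorm(n, 0, 0.01)
    ev <- evaluate_classifiers(matrix(x, ncol = 1), lab, seed = 1)
    for (r in ev$results) {
      expect_equal(r$auc, 1.0)
      expect_equal(r$sensitivity, 1.0)
      expect_equal(r$specificity, 1.0)
    }
  })
})

test_that("permuted labels give chance-level AUC", {
  withr::with_seed(71, {
    n <- 200
    x <- rnorm(n)
    lab <- factor(sample(rep(c("without_sas", "with_sas"), each = n / 2)),
                  levels = c("without_sas", "with_sas"))
    ev <- evaluate_classifiers(matrix(x, ncol = 1), lab,
                               algos = "lda", seed = 2)
    expect_lt(abs(ev$results$lda$auc - 0.5), 0.1)
  })
})

test_that("evaluate_classifiers rejects degenerate inputs", {
  lab <- factor(rep(c("without_sas", "with_sas"), each = 15),
                levels = c("without_sas", "with_sas"))
  expect_error(evaluate_classifiers(matrix(rep(1, 30), ncol = 1), lab),
               "zero variance")
  expect_error(
    evaluate_classifiers(matrix(rnorm(30), ncol = 1),
                         factor(rep("with_sas", 30))),
    "two classes")
  expect_error(evaluate_classifiers(matrix(rnorm(10), ncol = 1),
                                    lab[c(1:5, 16:20)]), "at least 20")
})

test_that("evaluation is reproducible given the seed", {
  withr::with_seed(73, {
    n <- 80
    lab <- factor(rep(c("without_sas", "with_sas"), each = n / 2),
                  levels = c("without_sas", "with_sas"))
    x <- rnorm(n) + (lab == "with_sas") * 1.5
  })
  e1 <- evaluate_classifiers(matrix(x, ncol = 1), lab, seed = 99)
  e2 <- evaluate_classifiers(matrix(x, ncol = 1), lab, seed = 99)
  expect_identical(vapply(e1$results, `[[`, numeric(1), "auc"),
                   vapply(e2$results, `[[`, numeric(1), "auc"))
})

test_that("adaboost learns a 1-D threshold rule", {
  withr::with_seed(79, {
    n <- 100
    y <- factor(rep(c("a", "b"), each = n / 2))
    x <- data.frame(f = rnorm(n) + (y == "b") * 3)
    fit <- adaboost_fit(x, y, positive = "b")
    pred <- predict(fit, x)
    expect_gt(mean(pred == y), 0.85)
    sc <- adaboost_score(fit, x)
    expect_gt(mean(sc[y == "b"]), mean(sc[y == "a"]))
  })
})
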