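test_that("recurrence_matrix applies the threshold rule", {
  R <- recurrence_matrix(c(0, 1, 0), 0.5)
  expect_equal(unclass(R)[1:3, 1:3],
               matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3),
               ignore_attr = TRUE)

  x <- c(3, 1, 4, 1, 5)
  Rall <- recurrence_matrix(x, max(dist(x)))
  expect_true(all(Rall == 1))

  # zero distance recurs even at epsilon = 0
  R0 <- recurrence_matrix(c(0, 1, 0), 0)
  expect_equal(unclass(R0)[1:3, 1:3],
               matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3),
               ignore_attr = TRUE)

  expect_error(recurrence_matrix(c(1, 2), -0.1), "non-negative")
})

test_that("recurrence matrices are symmetric with unit diagonal", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- rnorm(20)
      R <- recurrence_matrix(x, runif(1, 0.1, 2))
      expect_identical(unclass(R), t(unclass(R)))
      expect_true(all(diag(R) == 1))
    }
  })
})

test_that("diagonal_histogram counts maximal off-identity lines", {
  R <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3)
  h <- diagonal_histogram(R, theiler = 1)
  expect_equal(h$lengths, 1L)
  expect_equal(h$counts, 2L)

  h4 <- diagonal_histogram(matrix(1, 4, 4), theiler = 1)
  expect_equal(h4$lengths, 1:3)
  expect_equal(h4$counts, c(2L, 2L, 2L))

  hid <- diagonal_histogram(diag(5), theiler = 1)
  expect_length(hid$lengths, 0)
})

test_that("determinism follows the line-length weighting", {
  h <- structure(list(lengths = 1:3, counts = c(2L, 2L, 2L), theiler = 1L),
                 class = "diagonal_histogram")
  expect_equal(as.numeric(determinism(h, 2)), 10 / 12)
  expect_equal(as.numeric(determinism(h, 1)), 1.0)

  h1 <- structure(list(lengths = 1L, counts = 5L, theiler = 1L),
                  class = "diagonal_histogram")
  expect_equal(as.numeric(determinism(h1, 2)), 0.0)

  hempty <- diagonal_histogram(diag(4), theiler = 1)
  d <- determinism(hempty, 2)
  expect_equal(as.numeric(d), 0)
  expect_true(attr(d, "degenerate"))
})

test_that("det_curve matches the R-level composition on random series", {
  withr::with_seed(23, {
    for (i in 1:8) {
      x <- rnorm(40)
      lmin <- sample(1:5, 1)
      th <- sample(0:2, 1)
      grid <- default_eps_grid(x, n = 25)
      dc <- det_curve(x, grid, l_min = lmin, theiler = th)
      ref <- vapply(grid, function(e) {
        as.numeric(determinism(
          diagonal_histogram(recurrence_matrix(x, e), theiler = th), lmin))
      }, numeric(1))
      expect_equal(dc$det, ref)
    }
  })
})

test_that("det_curve handles constant, staircase and periodic series", {
  # constant series: every pair recurs, so DET is 1 at l_min = 1 and the
  # curve is flat (all-ones matrix) for any l_min
  dc1 <- det_curve(rep(5, 30), l_min = 1)
  expect_true(all(dc1$det == 1))
  dc10 <- det_curve(rep(5, 30), l_min = 10)
  expect_equal(diff(range(dc10$det)), 0)

  stair <- c(0, 10, 20, 30, 40)
  dstair <- det_curve(stair, eps_grid = c(1, 2, 3), l_min = 2)
  expect_true(all(dstair$det == 0))
  expect_true(all(dstair$recurrences == 0))

  sq <- rep(c(0, 1), 4)   # N = 8 alternating square wave
  dsq <- det_curve(sq, eps_grid = c(0.25, 0.5, 0.75), l_min = 2)
  expect_true(all(dsq$det == 1))
})

test_that("recurrence structure is nested and translation invariant", {
  withr::with_seed(31, {
    x <- rnorm(25)
    e1 <- 0.3; e2 <- 0.9
    R1 <- recurrence_matrix(x, e1)
    R2 <- recurrence_matrix(x, e2)
    expect_true(all(R1 <= R2))
    Rt <- recurrence_matrix(x + 57.3, e1)
    expect_equal(unclass(Rt)[seq_along(x), seq_along(x)],
                 unclass(R1)[seq_along(x), seq_along(x)])
  })
})

test_that("DET curves are scale equivariant and monotone in l_min", {
  withr::with_seed(37, {
    x <- rnorm(40)
    grid <- seq(0.1, 2, length.out = 20)
    a <- 3.7
    d1 <- det_curve(x, grid, l_min = 3)
    d2 <- det_curve(a * x, a * grid, l_min = 3)
    expect_equal(d1$det, d2$det)
    e1 <- epsilon_opt(d1); e2 <- epsilon_opt(d2)
    expect_equal(as.numeric(e2), a * as.numeric(e1))

    for (e in c(0.3, 0.8, 1.5)) {
      h <- diagonal_histogram(recurrence_matrix(x, e))
      dets <- vapply(1:6, function(l) as.numeric(determinism(h, l)),
                     numeric(1))
      expect_true(all(diff(dets) <= 1e-12))
    }
  })
})

test_that("total line-weighted count equals the off-Theiler recurrences", {
  withr::with_seed(41, {
    for (i in 1:5) {
      x <- sample(0:3, 15, replace = TRUE)
      e <- runif(1, 0.5, 2.5)
      R <- recurrence_matrix(x, e)
      h <- diagonal_histogram(R, theiler = 1)
      off <- sum(R) - sum(diag(R))
      expect_equal(sum(h$lengths * h$counts), off)
    }
  })
})

test_that("epsilon_opt finds the fastest DET rise with documented ties", {
  # single unit step between 0.4 and 0.5: the raw-curve estimator reports
  # the lower of the two grid points
  eps <- seq(0.1, 1, by = 0.1)
  det <- as.numeric(eps >= 0.5)
  curve <- structure(list(eps = eps, det = det,
                          recurrences = rep(1, 10), l_min = 2L,
                          theiler = 1L), class = "det_curve")
  e <- epsilon_opt(curve)
  expect_equal(as.numeric(e), 0.4)
  expect_false(attr(e, "degenerate"))

  # constant series: flat DET curve, degenerate flag, smallest grid value
  ec <- eps_opt_segment(rep(94, 50), fs = 1)
  expect_true(attr(ec, "degenerate"))
  expect_equal(as.numeric(ec), 0)
})

test_that("periodic segments need smaller thresholds than noise", {
  withr::with_seed(5, {
    t <- 1:300
    sine <- sqrt(2) * sin(2 * pi * t / 60)   # variance 1
    noise <- rnorm(300)                      # variance 1
    es <- eps_opt_segment(sine, fs = 1, l_min = 10)
    en <- eps_opt_segment(noise, fs = 1, l_min = 10)
    expect_lt(as.numeric(es), as.numeric(en))
  })
})

test_that("l_min defaults span about ten seconds of signal", {
  expect_equal(l_min_for_fs(1), 10L)
  expect_equal(l_min_for_fs(0.1), 2L)
})
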