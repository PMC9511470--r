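test_that("generation is deterministic given the seed", {
  cfg <- synthetic_config(duration_s = 600, seed = 7,
                          episodes = data.frame(start_s = 100, end_s = 400,
                                                kind = "ihhop"))
  a <- generate_record(cfg)
  b <- generate_record(cfg)
  expect_identical(a$record$values, b$record$values)
  expect_identical(a$truth$events, b$truth$events)
})

test_that("a noiseless episode-free record is a smooth quiet baseline", {
  cfg <- synthetic_config(duration_s = 3600, noise_sd = 0, seed = 3)
  sim <- generate_record(cfg)
  expect_lt(diff(range(sim$record$values)), 2 * 1.3 * 0.5 + 1e-6)
  expect_false(any(sim$truth$episode_mask))
  es <- rolling_eps_opt(preprocess_oximetry(sim$record), 300, 60)
  expect_true(all(!es$degenerate))
  expect_true(all(es$eps_opt < 0.2))
})

test_that("an ihhop train produces detectable desaturations inside it", {
  cfg <- synthetic_config(
    duration_s = 1800, noise_sd = 0, drift_amplitude = 0, seed = 5,
    episodes = data.frame(start_s = 600, end_s = 1200, kind = "ihhop",
                          depth = 6),
    cycle_period_range = c(60, 60))
  sim <- generate_record(cfg)
  ev <- detect_desaturations(sim$record, baseline = 94.3, N = 3)
  expect_gte(nrow(ev), 8)
  expect_true(all(ev$timestamp_s >= 600 & ev$timestamp_s <= 1200))
})

test_that("corpus baseline levels scatter around the configured mean", {
  corpus <- generate_corpus(50, mix = 0,
                            template = synthetic_config(duration_s = 300),
                            seed = 11)
  means <- vapply(corpus, function(z) z$truth$baseline_mean, numeric(1))
  expect_lt(abs(mean(means) - 94.3), 1.5)
  expect_gt(stats::sd(means), 0.5)   # between-record spread is present
})

test_that("episode and clean segments separate under re-derived thresholds", {
  corpus <- generate_corpus(60, mix = 0.5,
                            template = synthetic_config(duration_s = 300),
                            seed = 13)
  feats <- corpus_segment_features(corpus)
  ok <- !feats$degenerate
  thr <- ihhop_thresholds_from_corpus(feats$eps_opt[ok])
  cls <- classify_ihhop(feats$eps_opt[ok], thr)
  epi <- feats$has_episode[ok]

  # medians separate
  expect_gt(median(feats$eps_opt[ok][epi]), median(feats$eps_opt[ok][!epi]))
  # no clean segment lands in the top class; episodes do reach it
  expect_equal(sum(cls == "with" & !epi), 0)
  expect_gt(sum(cls == "with" & epi), 0)
})

test_that("biomarker and desaturation density co-move on episode sessions", {
  cr <- epsopt_odd_correlation(n_sessions = 2, session_s = 5400,
                               n_episodes_range = c(2, 3), seed = 17)
  expect_true(all(cr$per_session$r > 0))
})

test_that("the biomarker is robust to downsampling to 0.1 Hz", {
  cfg <- synthetic_config(
    duration_s = 5400, seed = 23,
    episodes = data.frame(start_s = c(1200, 3600),
                          end_s = c(2100, 4500), kind = "ihhop"))
  sim <- generate_record(cfg)
  pre1 <- preprocess_oximetry(sim$record)
  pre01 <- preprocess_oximetry(sim$record, block_s = 10)
  es1 <- rolling_eps_opt(pre1, 600, 60)     # l_min 10 @ 1 Hz
  es01 <- rolling_eps_opt(pre01, 600, 60)   # l_min 2 @ 0.1 Hz
  expect_equal(nrow(es1), nrow(es01))
  use <- !es1$degenerate & !es01$degenerate
  expect_gt(cor(es1$eps_opt[use], es01$eps_opt[use]), 0)
  # both rates put their maximum in a window overlapping an episode
  for (es in list(es1, es01)) {
    i <- which.max(ifelse(es$degenerate, -Inf, es$eps_opt))
    hit <- (es$window_start_s[i] < 2100 & es$window_end_s[i] > 1200) |
      (es$window_start_s[i] < 4500 & es$window_end_s[i] > 3600)
    expect_true(hit)
  }
})

test_that("invalid schedules are rejected", {
  expect_error(synthetic_config(
    duration_s = 600,
    episodes = data.frame(start_s = c(0, 100), end_s = c(200, 300),
                          kind = "ihhop")), "overlap")
  expect_error(synthetic_config(
    duration_s = 600,
    episodes = data.frame(start_s = 500, end_s = 700, kind = "ihhop")),
    "within the record")
  expect_error(synthetic_config(
    duration_s = 600,
    episodes = data.frame(start_s = 10, end_s = 100, kind = "nope")),
    "kind")
})
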