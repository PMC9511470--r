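#' Configuration for the synthetic oximetry generator
#'
#' The generator emulates intradialytic SaO2 recordings: a quasi-constant
#' saturation near 94.3% (between-record spread 2.1%) with slow smooth
#' drift and low-amplitude white measurement noise, interrupted by
#' scheduled episodes of either repetitive desaturation trains ("ihhop":
#' sawtooth cycles of 30-90 s period and 3-10 percentage-point depth, slow
#' desaturation / fast resaturation) or single rectangular desaturations
#' ("isolated_desat"). Depth and baseline are independent, so episodes may
#' or may not dip below 90% saturation. Noise is white and pre-filter; the
#' preprocessing low-pass is meant to be applied by the pipeline, not baked
#' in.
#'
#' @param duration_s record length in seconds.
#' @param fs sampling frequency in Hz, 1.0 or 0.1.
#' @param baseline_mean mean saturation level in percent.
#' @param baseline_sd between-record spread of the level (used by
#'   [generate_corpus()]; a single record uses `baseline_mean` as is).
#' @param noise_sd within-record white-noise standard deviation in percent.
#' @param drift_amplitude,drift_period_s amplitude (percent) and period (s)
#'   of the slow baseline drift.
#' @param episodes `NULL` or a data frame with columns `start_s`, `end_s`,
#'   `kind` (`"ihhop"` or `"isolated_desat"`) and optionally `depth`
#'   (percent; `NA` draws from `dip_depth_range`). Episodes must lie within
#'   the record and not overlap.
#' @param cycle_period_range sawtooth cycle period range in seconds.
#' @param dip_depth_range dip depth range in percentage points.
#' @param waveform `"sawtooth"` (default) or `"sine"` dip shape.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(duration_s = 3600, fs = 1,
                             baseline_mean = 94.3, baseline_sd = 2.1,
                             noise_sd = 0.3,
                             drift_amplitude = 0.5, drift_period_s = 1800,
                             episodes = NULL,
                             cycle_period_range = c(30, 90),
                             dip_depth_range = c(3, 10),
                             waveform = c("sawtooth", "sine"),
                             seed = NULL) {
  waveform <- match.arg(waveform)
  if (!fs %in% c(1.0, 0.1)) stop("'fs' must be 1.0 or 0.1 Hz")
  if (duration_s * fs < 2) stop("record too short")
  if (!is.null(episodes)) {
    episodes <- as.data.frame(episodes)
    if (!all(c("start_s", "end_s", "kind") %in% names(episodes))) {
      stop("'episodes' needs columns start_s, end_s, kind")
    }
    if (is.null(episodes$depth)) episodes$depth <- NA_real_
    if (any(episodes$end_s <= episodes$start_s)) {
      stop("episodes need start_s < end_s")
    }
    if (any(episodes$start_s < 0) || any(episodes$end_s > duration_s)) {
      stop("episodes must lie within the record span")
    }
    ord <- order(episodes$start_s)
    episodes <- episodes[ord, , drop = FALSE]
    if (nrow(episodes) > 1 &&
        any(episodes$start_s[-1] < episodes$end_s[-nrow(episodes)])) {
      stop("episodes must not overlap")
    }
    if (any(!episodes$kind %in% c("ihhop", "isolated_desat"))) {
      stop("episode kind must be 'ihhop' or 'isolated_desat'")
    }
    if (any(!is.na(episodes$depth) & episodes$depth <= 0)) {
      stop("episode depths must be positive")
    }
  }
  if (any(dip_depth_range <= 0)) stop("dip depths must be positive")
  structure(list(duration_s = duration_s, fs = fs,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s, episodes = episodes,
                 cycle_period_range = cycle_period_range,
                 dip_depth_range = dip_depth_range, waveform = waveform,
                 seed = seed),
            class = "synthetic_config")
}

# Dip profile over one cycle: phase in [0, 1); sawtooth descends linearly
# over the first 80% of the cycle and recovers over the last 20%.
dip_profile <- function(phase, depth, waveform) {
  if (waveform == "sawtooth") {
    f <- 0.8
    ifelse(phase < f, depth * phase / f, depth * (1 - phase) / (1 - f))
  } else {
    depth / 2 * (1 - cos(2 * pi * phase))
  }
}

#' Generate a synthetic oximetry record with ground truth
#'
#' @param config a [synthetic_config()].
#' @return a list with elements `record` (an [oximetry_record()]) and
#'   `truth`: per-sample logical `episode_mask`, a data frame `events` of
#'   injected dips (`onset_s`, `duration_s`, `depth_pct`, `kind`), and the
#'   record's clean `baseline_mean`.
#' @examples
#' cfg <- synthetic_config(duration_s = 600, seed = 1,
#'   episodes = data.frame(start_s = 120, end_s = 480, kind = "ihhop"))
#' out <- generate_record(cfg)
#' out$record
#' @export
generate_record <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  gen <- function() {
    fs <- config$fs
    n <- as.integer(round(config$duration_s * fs))
    t <- (seq_len(n) - 1) / fs
    ph <- runif(2, 0, 2 * pi)
    drift <- config$baseline_mean +
      config$drift_amplitude * sin(2 * pi * t / config$drift_period_s + ph[1]) +
      0.3 * config$drift_amplitude *
        sin(2 * pi * t / (config$drift_period_s / 3) + ph[2])
    dip <- numeric(n)
    mask <- logical(n)
    events <- list()
    eps <- config$episodes
    if (!is.null(eps)) {
      for (r in seq_len(nrow(eps))) {
        s0 <- eps$start_s[r]; e0 <- eps$end_s[r]
        kind <- eps$kind[r]
        in_ep <- t >= s0 & t < e0
        mask <- mask | in_ep
        if (kind == "isolated_desat") {
          d <- if (is.na(eps$depth[r])) {
            runif(1, config$dip_depth_range[1], config$dip_depth_range[2])
          } else eps$depth[r]
          dip[in_ep] <- dip[in_ep] + d
          events[[length(events) + 1]] <-
            data.frame(onset_s = s0, duration_s = e0 - s0, depth_pct = d,
                       kind = kind)
        } else {
          c0 <- s0
          while (c0 < e0) {
            Tc <- runif(1, config$cycle_period_range[1],
                        config$cycle_period_range[2])
            d <- if (is.na(eps$depth[r])) {
              runif(1, config$dip_depth_range[1], config$dip_depth_range[2])
            } else eps$depth[r]
            cyc <- t >= c0 & t < min(c0 + Tc, e0)
            if (any(cyc)) {
              phase <- (t[cyc] - c0) / Tc
              dip[cyc] <- dip[cyc] + dip_profile(phase, d, config$waveform)
            }
            events[[length(events) + 1]] <-
              data.frame(onset_s = c0, duration_s = Tc, depth_pct = d,
                         kind = kind)
            c0 <- c0 + Tc
          }
        }
      }
    }
    values <- drift - dip + rnorm(n, 0, config$noise_sd)
    values <- pmin(pmax(values, 0), 100)
    list(
      record = oximetry_record(values, fs = fs),
      truth = list(
        episode_mask = mask,
        events = if (length(events)) do.call(rbind, events) else
          data.frame(onset_s = numeric(0), duration_s = numeric(0),
                     depth_pct = numeric(0), kind = character(0)),
        baseline_mean = config$baseline_mean,
        config = config))
  }
  if (is.null(config$seed)) gen() else withr::with_seed(config$seed, gen())
}

# Draw a non-overlapping episode schedule: n episodes with durations from
# `duration_range`, first start >= min_start, gaps >= gap_s, jittered into
# the available slack.
random_episode_schedule <- function(duration_s, n_episodes,
                                    duration_range, min_start = 0,
                                    gap_s = 60, kind = "ihhop") {
  durs <- runif(n_episodes, duration_range[1], duration_range[2])
  total <- sum(durs) + gap_s * (n_episodes - 1)
  avail <- duration_s - min_start
  if (total > avail) {
    durs <- durs * (avail - gap_s * (n_episodes - 1)) / sum(durs)
    if (any(durs <= 0)) stop("episode schedule does not fit the record")
    total <- sum(durs) + gap_s * (n_episodes - 1)
  }
  slack <- avail - total
  pos <- min_start
  out <- vector("list", n_episodes)
  for (j in seq_len(n_episodes)) {
    pos <- pos + runif(1, 0, slack / n_episodes)
    out[[j]] <- data.frame(start_s = pos, end_s = pos + durs[j],
                           kind = kind, depth = NA_real_)
    pos <- pos + durs[j] + gap_s
  }
  do.call(rbind, out)
}

#' Generate a corpus of synthetic records
#'
#' Draws `n_records` records from a template configuration: per-record
#' baseline levels come from `Normal(baseline_mean, baseline_sd)`, a
#' `mix` fraction of records receives randomized episode schedules within
#' the template bounds, and every record's seed is derived reproducibly
#' from the master seed.
#'
#' @param n_records number of records (>= 2).
#' @param mix fraction of records containing episodes, in `[0, 1]`.
#' @param template a [synthetic_config()] giving duration, rates, noise and
#'   episode parameter ranges (its `episodes`/`seed` fields are ignored).
#' @param episode_opts list controlling the randomized schedules:
#'   `n_range` (episode count range), `duration_range` in seconds (`NULL`
#'   means one episode spanning the whole record past `min_start`),
#'   `min_start` (earliest episode start, seconds; keep at least the
#'   baseline head clean for full sessions), `gap_s` (minimum gap).
#' @param seed master seed.
#' @return list of `n_records` elements, each `list(record, truth)`, with
#'   attributes `mix` and `seed`.
#' @export
generate_corpus <- function(n_records, mix = 0.5,
                            template = synthetic_config(duration_s = 300),
                            episode_opts = list(), seed = NULL) {
  stopifnot(inherits(template, "synthetic_config"))
  if (n_records < 2) stop("'n_records' must be >= 2")
  if (mix < 0 || mix > 1) stop("'mix' must be in [0, 1]")
  eo <- utils::modifyList(
    list(n_range = c(1, 1), duration_range = NULL, min_start = 0,
         gap_s = 60), episode_opts)
  gen <- function() {
    n_ep <- round(mix * n_records)
    flags <- sample(rep(c(TRUE, FALSE), c(n_ep, n_records - n_ep)))
    lapply(seq_len(n_records), function(i) {
      bm <- rnorm(1, template$baseline_mean, template$baseline_sd)
      episodes <- NULL
      if (flags[i]) {
        k <- if (eo$n_range[1] == eo$n_range[2]) eo$n_range[1] else
          sample(seq(eo$n_range[1], eo$n_range[2]), 1)
        dr <- if (is.null(eo$duration_range)) {
          rep(template$duration_s - eo$min_start, 2)
        } else eo$duration_range
        episodes <- random_episode_schedule(
          template$duration_s, k, dr, min_start = eo$min_start,
          gap_s = eo$gap_s)
      }
      cfg <- template
      cfg$baseline_mean <- bm
      cfg$episodes <- episodes
      cfg$seed <- derive_seed(if (is.null(seed)) 0 else seed, i)
      # re-validate through the constructor
      cfg <- synthetic_config(
        duration_s = cfg$duration_s, fs = cfg$fs, baseline_mean = bm,
        baseline_sd = cfg$baseline_sd, noise_sd = cfg$noise_sd,
        drift_amplitude = cfg$drift_amplitude,
        drift_period_s = cfg$drift_period_s, episodes = episodes,
        cycle_period_range = cfg$cycle_period_range,
        dip_depth_range = cfg$dip_depth_range, waveform = cfg$waveform,
        seed = cfg$seed)
      generate_record(cfg)
    })
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  attr(out, "mix") <- mix
  attr(out, "seed") <- seed
  out
}
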