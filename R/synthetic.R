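#' Synthetic labelled IMU recordings
#'
#' Generates multi-sensor recordings with ground-truth interaction labels so
#' the full detection pipeline can be exercised end to end. The label
#' sequence follows a semi-Markov process (explicit log-normal dwell times)
#' over the five interaction categories, calibrated so that independent
#' movement dominates (~85% occupancy) and most interaction segments last a
#' few seconds. The signal model encodes the physical premise that carrying
#' must be sensed through movement: a slowly wandering gravity orientation
#' per sensor, independent band-limited limb bursts during independent
#' movement, a low-frequency oscillation shared across all sensors while the
#' caregiver moves the infant (strongest in active carry, present in active
#' support, weak postural sway in passive carry), attenuated limb activity
#' during contact states, and white sensor noise. Simulated annotators apply
#' boundary jitter, per-segment label confusion, and out-of-screen
#' insertions to the truth.
#'
#' @name synthetic
NULL

default_annotator_confusion <- function() {
  ## rows = true category, columns = assigned category; AS deliberately the
  ## most confusable, IM and AC the most reliable
  m <- matrix(c(
    0.97, 0.02, 0.01, 0.00, 0.00,   # IM
    0.10, 0.80, 0.05, 0.05, 0.00,   # PS
    0.05, 0.10, 0.70, 0.05, 0.10,   # AS
    0.02, 0.08, 0.05, 0.80, 0.05,   # PC
    0.00, 0.00, 0.05, 0.05, 0.90),  # AC
    5, 5, byrow = TRUE,
    dimnames = list(CH_CATEGORIES, CH_CATEGORIES))
  m
}

#' Synthetic-data configuration
#'
#' Defaults define the reference study conditions used throughout the
#' package's tests: category occupancies near IM 86% / PS 5.6% / AS 2.5% /
#' PC 2.1% / AC 3.5%, interaction dwell times of a few seconds, gravity
#' 9.81 m/s^2, and a 0.5-2 Hz shared carry oscillation.
#'
#' @param duration_s recording length in seconds.
#' @param rate_hz sampling rate.
#' @param dwell_mean_s named mean dwell times (s) per category.
#' @param dwell_sdlog log-normal dwell spread.
#' @param transition_w named transition weights from IM into the four
#'   interaction categories.
#' @param cross_prob probability that an interaction segment is followed by
#'   another interaction category instead of returning to IM.
#' @param gravity gravity magnitude (m/s^2).
#' @param orient_walk named per-category orientation random-walk step scale
#'   (rad/sample).
#' @param burst_rate_hz limb-burst event rate per sensor during independent
#'   movement (events/s).
#' @param burst_amp limb-burst amplitude scale (m/s^2).
#' @param limb_band_hz frequency band of limb-burst noise.
#' @param limb_gain named per-category attenuation of limb activity.
#' @param shared_amp shared carry-oscillation amplitude scale (m/s^2).
#' @param shared_band_hz frequency band of the shared oscillation.
#' @param shared_gain named per-category gain of the shared oscillation.
#' @param noise_sd white sensor noise sd (m/s^2).
#' @param gyro_noise_sd gyroscope white noise sd (rad/s).
#' @param ann_jitter_sd annotator boundary jitter sd (s).
#' @param ann_confusion 5x5 annotator label confusion matrix (rows sum to 1).
#' @param oos_rate_per_min annotator out-of-screen insertions per minute.
#' @param oos_dwell_s mean out-of-screen duration (s).
#' @return object of class `ch_synth_config`.
#' @export
synth_config <- function(duration_s = 600, rate_hz = 52,
                         dwell_mean_s = c(IM = 26, PS = 4, AS = 3,
                                          PC = 6, AC = 5),
                         dwell_sdlog = 0.8,
                         transition_w = c(PS = 0.426, AS = 0.254,
                                          PC = 0.107, AC = 0.213),
                         cross_prob = 0.15,
                         gravity = 9.81,
                         orient_walk = c(IM = 0.002, PS = 0.001, AS = 0.006,
                                         PC = 0.001, AC = 0.010),
                         burst_rate_hz = 0.4, burst_amp = 3.0,
                         limb_band_hz = c(2, 8),
                         limb_gain = c(IM = 1, PS = 0.3, AS = 0.6,
                                       PC = 0.08, AC = 0.15),
                         shared_amp = 2.0, shared_band_hz = c(0.5, 2),
                         shared_gain = c(IM = 0, PS = 0.03, AS = 0.8,
                                         PC = 0.3, AC = 1.0),
                         noise_sd = 0.05, gyro_noise_sd = 0.02,
                         ann_jitter_sd = 0.3,
                         ann_confusion = default_annotator_confusion(),
                         oos_rate_per_min = 0.5, oos_dwell_s = 5) {
  stopifnot(duration_s > 0, rate_hz > 0, all(dwell_mean_s > 0),
            all(transition_w >= 0), all(limb_gain >= 0),
            all(shared_gain >= 0), noise_sd >= 0)
  ann_confusion <- as.matrix(ann_confusion)
  if (!all(dim(ann_confusion) == c(5L, 5L))) {
    stop("annotator confusion must be 5 x 5")
  }
  if (any(abs(rowSums(ann_confusion) - 1) > 1e-9)) {
    stop("annotator confusion rows must sum to 1")
  }
  dimnames(ann_confusion) <- list(CH_CATEGORIES, CH_CATEGORIES)
  structure(as.list(environment()), class = "ch_synth_config")
}

#' Sample a ground-truth label track
#'
#' Semi-Markov process: IM alternates with interaction segments; dwell times
#' are log-normal with the configured means; after an interaction segment
#' the process returns to IM or (with `cross_prob`) moves directly to
#' another interaction category.
#'
#' @param cfg a [synth_config()].
#' @param seed RNG seed; `(cfg, seed)` fully determine the track.
#' @param duration_s optional override of `cfg$duration_s`.
#' @return a `ch_track` (annotator id `"truth"`, no OOS).
#' @export
sample_labels <- function(cfg, seed = 1L, duration_s = NULL) {
  stopifnot(inherits(cfg, "ch_synth_config"))
  set.seed(seed)
  dur <- if (is.null(duration_s)) cfg$duration_s else duration_s
  rdwell <- function(cat_) {
    m <- cfg$dwell_mean_s[[cat_]]
    max(0.5, stats::rlnorm(1, log(m) - cfg$dwell_sdlog^2 / 2, cfg$dwell_sdlog))
  }
  w <- cfg$transition_w[c("PS", "AS", "PC", "AC")]
  segs <- list()
  t <- 0; state <- "IM"
  while (t < dur) {
    d <- rdwell(state)
    segs[[length(segs) + 1L]] <- data.frame(start_s = t,
                                            end_s = min(t + d, dur),
                                            category = state)
    t <- t + d
    if (t >= dur) break
    if (state == "IM") {
      if (sum(w) <= 0) {          # no way out of IM: extend to full duration
        segs[[length(segs)]]$end_s <- dur
        break
      }
      state <- sample(names(w), 1L, prob = w)
    } else {
      if (stats::runif(1) < cfg$cross_prob && sum(w) > 0) {
        w2 <- w[names(w) != state]
        state <- if (sum(w2) > 0) sample(names(w2), 1L, prob = w2) else "IM"
      } else {
        state <- "IM"
      }
    }
  }
  iv <- do.call(rbind, segs)
  ## merge any adjacent same-category segments created by dead-end branches
  annotation_track(iv, annotator_id = "truth")
}

## band-limited unit-variance noise
bl_noise <- function(n, band_hz, rate_hz) {
  x <- stats::rnorm(n)
  y <- zero_phase_filter(x, filter_spec("band_pass", 4, band_hz), rate_hz)
  y / max(stats::sd(y), 1e-12)
}

## burst envelope: Hann bumps at Poisson times
burst_envelope <- function(n, rate_hz, events_per_s) {
  env <- numeric(n)
  n_ev <- stats::rpois(1, events_per_s * n / rate_hz)
  if (n_ev == 0) return(env)
  centers <- sort(stats::runif(n_ev, 0, n / rate_hz))
  for (ct in centers) {
    width <- stats::runif(1, 0.3, 1.0)
    amp <- stats::runif(1, 0.5, 1.5)
    i0 <- max(1L, round((ct - width / 2) * rate_hz))
    i1 <- min(n, round((ct + width / 2) * rate_hz))
    if (i1 <= i0) next
    idx <- i0:i1
    env[idx] <- pmax(env[idx],
                     amp * 0.5 * (1 - cos(2 * pi * seq(0, 1,
                                                       length.out = length(idx)))))
  }
  env
}

## per-sample category code from a track (1..5 over CH_CATEGORIES; OOS and
## uncovered time inherit the previous state for signal generation)
state_codes <- function(track, n, rate_hz) {
  t <- (seq_len(n) - 0.5) / rate_hz
  iv <- track$intervals
  iv <- iv[iv$category != CH_OOS, , drop = FALSE]
  code <- integer(n)
  for (i in seq_len(nrow(iv))) {
    sel <- t >= iv$start_s[i] & t < iv$end_s[i]
    code[sel] <- match(iv$category[i], CH_CATEGORIES)
  }
  ## fill any zeros (OOS gaps) with the nearest previous state
  if (all(code == 0L)) return(rep(1L, n))
  if (any(code == 0L)) {
    last <- code[which(code > 0L)[1]]
    for (i in seq_len(n)) {
      if (code[i] == 0L) code[i] <- last else last <- code[i]
    }
  }
  code
}

#' Synthesize a multi-sensor recording for a label track
#'
#' @param track a `ch_track` covering the duration (typically from
#'   [sample_labels()]).
#' @param cfg a [synth_config()].
#' @param seed RNG seed.
#' @param id recording id.
#' @return a `ch_recording` with four sensors.
#' @export
synthesize_recording <- function(track, cfg, seed = 1L, id = "synth") {
  stopifnot(inherits(track, "ch_track"), inherits(cfg, "ch_synth_config"))
  set.seed(seed + 1L)
  dur <- diff(track$span)
  if (abs(dur - cfg$duration_s) > 1 / cfg$rate_hz &&
      dur < cfg$duration_s - 1e-9) {
    stop(sprintf("track duration %.1f s does not cover cfg duration %.1f s",
                 dur, cfg$duration_s))
  }
  rate <- cfg$rate_hz
  n <- round(dur * rate)
  code <- state_codes(track, n, rate)
  limb_g <- cfg$limb_gain[CH_CATEGORIES][code]
  shared_g <- cfg$shared_gain[CH_CATEGORIES][code]
  orient_g <- cfg$orient_walk[CH_CATEGORIES][code]
  shared <- bl_noise(n, cfg$shared_band_hz, rate)
  data <- list()
  for (s in CH_PLACEMENTS) {
    coupling <- stats::runif(1, 0.7, 1)
    sdir <- stats::rnorm(3); sdir <- sdir / sqrt(sum(sdir^2))
    ## orientation: random walk on a 3-vector, renormalized to unit length
    steps <- matrix(stats::rnorm(n * 3), n, 3) * orient_g
    v <- apply(steps, 2, cumsum)
    v0 <- stats::rnorm(3); v0 <- v0 / sqrt(sum(v0^2))
    v <- sweep(v, 2, v0, "+")
    nv <- sqrt(rowSums(v^2))
    u <- v / pmax(nv, 1e-9)
    env <- burst_envelope(n, rate, cfg$burst_rate_hz)
    acc <- matrix(0, n, 3)
    gyro <- matrix(0, n, 3)
    for (ax in 1:3) {
      limb <- bl_noise(n, cfg$limb_band_hz, rate) * env * limb_g *
        cfg$burst_amp
      ## the shared oscillation is dominantly vertical (a locomotion bounce
      ## along gravity) with a smaller fixed horizontal component
      shared_dir <- 0.8 * u[, ax] + 0.2 * sdir[ax]
      acc[, ax] <- cfg$gravity * u[, ax] +
        cfg$shared_amp * shared_g * coupling * shared_dir * shared +
        limb + stats::rnorm(n, sd = cfg$noise_sd)
      ## angular velocity: differentiated orientation + movement-coupled and
      ## white noise
      dang <- c(0, diff(u[, ax])) * rate
      gyro[, ax] <- dang + 0.05 * limb +
        stats::rnorm(n, sd = cfg$gyro_noise_sd)
    }
    data[[s]] <- list(acc = acc, gyro = gyro)
  }
  recording(data, rate_hz = rate, id = id, start_time = 0)
}

#' Simulate a human annotator
#'
#' Applies zero-mean Gaussian jitter to segment boundaries, resamples each
#' segment's label from the confusion row of its true category, and inserts
#' out-of-screen periods at the configured rate.
#'
#' @param track ground-truth `ch_track`.
#' @param cfg a [synth_config()].
#' @param seed RNG seed.
#' @param annotator_id id for the simulated annotator.
#' @return a `ch_track`.
#' @export
simulate_annotator <- function(track, cfg, seed = 1L, annotator_id = "sim") {
  stopifnot(inherits(track, "ch_track"), inherits(cfg, "ch_synth_config"))
  set.seed(seed + 2L)
  iv <- track$intervals[track$intervals$category != CH_OOS, , drop = FALSE]
  span <- track$span
  ## jitter interior boundaries, preserving order
  bounds <- c(iv$start_s[1], iv$end_s)
  if (length(bounds) > 2L && cfg$ann_jitter_sd > 0) {
    interior <- 2:(length(bounds) - 1L)
    bounds[interior] <- bounds[interior] +
      stats::rnorm(length(interior), sd = cfg$ann_jitter_sd)
    bounds <- cummax(pmin(pmax(bounds, span[1]), span[2]))
  }
  cats <- iv$category
  ## per-segment label confusion
  cm <- cfg$ann_confusion
  cats <- vapply(cats, function(ct) {
    sample(CH_CATEGORIES, 1L, prob = cm[ct, ])
  }, character(1))
  keep <- diff(bounds) > 1e-6
  out <- data.frame(start_s = bounds[-length(bounds)][keep],
                    end_s = bounds[-1][keep], category = cats[keep])
  ## overlay OOS insertions
  n_oos <- stats::rpois(1, cfg$oos_rate_per_min * diff(span) / 60)
  if (n_oos > 0) {
    for (k in seq_len(n_oos)) {
      d <- stats::rexp(1, 1 / cfg$oos_dwell_s)
      st <- stats::runif(1, span[1], max(span[1], span[2] - d))
      out <- overlay_interval(out, st, min(st + d, span[2]), CH_OOS)
    }
  }
  annotation_track(out, annotator_id = annotator_id, span = span)
}

## punch an interval into a non-overlapping interval table
overlay_interval <- function(iv, start_s, end_s, category) {
  pieces <- list()
  for (i in seq_len(nrow(iv))) {
    s <- iv$start_s[i]; e <- iv$end_s[i]
    if (e <= start_s || s >= end_s) {
      pieces[[length(pieces) + 1L]] <- iv[i, ]
      next
    }
    if (s < start_s) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(start_s = s, end_s = start_s, category = iv$category[i])
    }
    if (e > end_s) {
      pieces[[length(pieces) + 1L]] <-
        data.frame(start_s = end_s, end_s = e, category = iv$category[i])
    }
  }
  pieces[[length(pieces) + 1L]] <-
    data.frame(start_s = start_s, end_s = end_s, category = category)
  out <- do.call(rbind, pieces)
  out[order(out$start_s), , drop = FALSE]
}

#' Reference low-band correlation carry detector
#'
#' An analytic oracle used to confirm that the carrying state is in
#' principle recoverable from generated signals before any model training:
#' per frame, the mean pairwise Pearson correlation of the 0.5-2 Hz
#' band-passed accelerometer magnitudes across sensors. Carried frames show
#' a shared oscillation and hence high correlation.
#'
#' @param rec a `ch_recording` with at least 2 sensors.
#' @param cfg a [framing_config()].
#' @param band_hz analysis band.
#' @return numeric vector, one correlation per frame.
#' @export
carry_correlation_feature <- function(rec, cfg = framing_config(),
                                      band_hz = c(0.5, 2)) {
  stopifnot(inherits(rec, "ch_recording"))
  if (length(rec$sensors) < 2L) stop("need at least 2 sensors")
  spec <- filter_spec("band_pass", 4, band_hz)
  mags <- vapply(rec$sensors, function(s) {
    zero_phase_filter(magnitude(rec$data[[s]]$acc), spec, rec$rate_hz)
  }, numeric(rec$n_samples))
  nf <- n_frames_for(rec$n_samples, cfg)
  out <- numeric(nf)
  pairs <- utils::combn(ncol(mags), 2)
  for (f in seq_len(nf)) {
    sel <- (f - 1L) * cfg$hop_samples + seq_len(cfg$frame_len_samples)
    w <- mags[sel, , drop = FALSE]
    cc <- vapply(seq_len(ncol(pairs)), function(p) {
      suppressWarnings(stats::cor(w[, pairs[1, p]], w[, pairs[2, p]]))
    }, numeric(1))
    out[f] <- mean(cc, na.rm = TRUE)
  }
  out[!is.finite(out)] <- 0
  out
}

#' Generate a full synthetic dataset
#'
#' @param n_recordings number of recordings.
#' @param cfg a [synth_config()].
#' @param seed base seed; recording `i` uses `seed + 1000 * i` offsets.
#' @param n_annotators simulated annotators per recording (0 for truth only).
#' @return list of entries `list(id, rec, truth, annotations)`.
#' @export
synth_dataset <- function(n_recordings, cfg = synth_config(), seed = 1L,
                          n_annotators = 2L) {
  lapply(seq_len(n_recordings), function(i) {
    s <- seed + 1000L * i
    id <- sprintf("synth%03d", i)
    truth <- sample_labels(cfg, seed = s)
    rec <- synthesize_recording(truth, cfg, seed = s + 1L, id = id)
    anns <- lapply(seq_len(n_annotators), function(a) {
      simulate_annotator(truth, cfg, seed = s + 10L * a,
                         annotator_id = sprintf("a%d", a))
    })
    list(id = id, rec = rec, truth = truth, annotations = anns)
  })
}
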