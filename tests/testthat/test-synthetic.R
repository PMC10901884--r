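test_that("label sampling is deterministic and honours degenerate configs", {
  cfg <- synth_config(duration_s = 300)
  t1 <- sample_labels(cfg, seed = 5)
  t2 <- sample_labels(cfg, seed = 5)
  expect_identical(t1$intervals, t2$intervals)
  # no transitions out of IM -> one IM segment spanning the duration
  cfg0 <- synth_config(duration_s = 300,
                       transition_w = c(PS = 0, AS = 0, PC = 0, AC = 0))
  t0 <- sample_labels(cfg0, seed = 1)
  expect_equal(nrow(t0$intervals), 1L)
  expect_equal(t0$intervals$category, "IM")
  expect_equal(diff(t0$span), 300)
})

test_that("default label process matches the study conditions", {
  cfg <- synth_config()
  occ <- sapply(1:10, function(i) {
    iv <- sample_labels(cfg, seed = i, duration_s = 3600)$intervals
    sum((iv$end_s - iv$start_s)[iv$category == "IM"]) / sum(iv$end_s - iv$start_s)
  })
  expect_gte(mean(occ), 0.80)
  expect_lte(mean(occ), 0.90)
  # most interaction segments are seconds-scale: >= 40% within [1, 5] s
  segs <- unlist(lapply(1:5, function(i) {
    sl <- segment_lengths(sample_labels(cfg, seed = 100 + i,
                                        duration_s = 1800),
                          label_scheme("raw5"))
    unlist(sl[c("PS", "AS", "PC", "AC")])
  }))
  expect_gte(mean(segs >= 1 & segs <= 5), 0.40)
})

test_that("the signal model encodes the carry signature", {
  cfg <- synth_config(duration_s = 240)
  fcfg <- framing_config()
  # gravity only: constant norm 9.81 without noise or movement
  quiet <- synth_config(duration_s = 60, noise_sd = 0, gyro_noise_sd = 0,
                        burst_rate_hz = 0,
                        orient_walk = c(IM = 0, PS = 0, AS = 0, PC = 0,
                                        AC = 0),
                        shared_gain = c(IM = 0, PS = 0, AS = 0, PC = 0,
                                        AC = 0))
  tr <- annotation_track(data.frame(start_s = 0, end_s = 60,
                                    category = "IM"))
  rq <- synthesize_recording(tr, quiet, seed = 2)
  expect_equal(magnitude(rq$data$left_arm$acc),
               rep(9.81, rq$n_samples), tolerance = 1e-9)
  # carried frames correlate across sensors; independent movement does not
  trAC <- annotation_track(data.frame(start_s = 0, end_s = 240,
                                      category = "AC"))
  fAC <- carry_correlation_feature(synthesize_recording(trAC, cfg, seed = 7),
                                   fcfg)
  expect_gt(mean(fAC), 0.5)
  trIM <- annotation_track(data.frame(start_s = 0, end_s = 240,
                                      category = "IM"))
  fIM <- carry_correlation_feature(synthesize_recording(trIM, cfg, seed = 8),
                                   fcfg)
  expect_lt(mean(fIM), 0.2)
})

test_that("generation is fully determined by (config, seed)", {
  cfg <- synth_config(duration_s = 120)
  tr <- sample_labels(cfg, seed = 3)
  r1 <- synthesize_recording(tr, cfg, seed = 4)
  r2 <- synthesize_recording(tr, cfg, seed = 4)
  expect_identical(r1$data, r2$data)
  a1 <- simulate_annotator(tr, cfg, seed = 5)
  a2 <- simulate_annotator(tr, cfg, seed = 5)
  expect_identical(a1$intervals, a2$intervals)
})

test_that("the carry state is recoverable by the correlation oracle", {
  # label/signal consistency: before any model training, a low-band
  # inter-sensor correlation threshold recovers def2 carrying
  cfg <- synth_config()
  fcfg <- framing_config()
  feats <- c(); refs <- c()
  for (i in 1:3) {
    tr <- sample_labels(cfg, seed = 20 + i)
    rec <- synthesize_recording(tr, cfg, seed = 40 + i)
    fl <- to_frame_labels(tr, frame_times(rec$n_samples, fcfg),
                          label_scheme("def2"))
    feats <- c(feats, carry_correlation_feature(rec, fcfg))
    refs <- c(refs, fl$class_idx)
  }
  sw <- threshold_sweep(feats, refs)
  expect_gte(sw$best$kappa, 0.6)
})

test_that("simulated annotators degrade gracefully with noise", {
  cfg <- synth_config(duration_s = 600)
  fcfg <- framing_config()
  tr <- sample_labels(cfg, seed = 31)
  times <- frame_times(round(600 * 52), fcfg)
  truth_fl <- to_frame_labels(tr, times, label_scheme("raw5"))
  # moderate jitter with identity confusion stays close to truth
  cfg_j <- synth_config(duration_s = 600, ann_jitter_sd = 0.5,
                        ann_confusion = diag(5), oos_rate_per_min = 0)
  ks <- sapply(1:10, function(s) {
    a <- simulate_annotator(tr, cfg_j, seed = 100 + s)
    fl <- to_frame_labels(a, times, label_scheme("raw5"))
    kappa_multiclass(confusion(fl, truth_fl))
  })
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1)
})
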