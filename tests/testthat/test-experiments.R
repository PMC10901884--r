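test_that("paired t-tests match hand computation and handle degeneracy", {
  # differences (0.1, 0.2, 0.3, 0.2): t = 0.2 / (sd/2) = 4.899, df = 3
  b <- c(0.5, 0.5, 0.5, 0.5)
  a <- b + c(0.1, 0.2, 0.3, 0.2)
  tt <- paired_ttest(a, b)
  expect_equal(round(tt$t, 3), 4.899)
  expect_equal(tt$df, 3)
  # matches stats::t.test directly
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(tt$t, unname(ref$statistic))
  expect_equal(tt$p, ref$p.value)
  # swapping negates t, preserves p
  ts <- paired_ttest(b, a)
  expect_equal(ts$t, -tt$t)
  expect_equal(ts$p, tt$p)
  # identical vectors
  t0 <- paired_ttest(b, b)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  # constant nonzero differences: flagged infinite t
  tc <- paired_ttest(b + 1, b)
  expect_true(is.infinite(tc$t))
  expect_equal(tc$flag, "zero variance of differences")
  expect_error(paired_ttest(1:3, 1:4), "equal length")
})

test_that("the ablation grid validates axes and names subsets", {
  g <- ablation_grid()
  expect_equal(g$scheme, "def2")
  expect_true("all4" %in% names(g$sensor_subsets))
  expect_error(ablation_grid(sensor_subsets = list()), "non-empty")
  expect_error(ablation_grid(sensor_subsets = list(c("head"))), "unknown")
})

test_that("a one-cell ablation reduces to plain cross-validation with shared folds", {
  cfg <- synth_config(duration_s = 300)
  ds <- synth_dataset(4, cfg, seed = 55, n_annotators = 0)
  grid <- ablation_grid(sensor_subsets = list(all4 = CH_PLACEMENTS,
                                              one_arm = "left_arm"),
                        rates = 52, modalities = "acc_gyro")
  mcfg_fn <- function(n_sensors, heads) {
    model_config(n_sensors = n_sensors, active_heads = heads,
                 latent_dim = 8, enc_filters = c(3, 4))
  }
  tcfg <- training_config(epochs = 2, learning_rate = 1e-3, seed = 5,
                          n_folds = 4)
  ab <- run_ablation(ds, grid, mcfg_fn, tcfg, use_truth = TRUE)
  expect_equal(nrow(ab$results), 8L)          # 2 cells x 4 folds
  expect_true(all(table(ab$results$subset) == 4))
  # identical fold partition across cells (pairing precondition): the
  # direct cross-validation of the same items reproduces the cell's scores
  items <- prepare_items(ds, scheme = "def2", use_truth = TRUE)
  cv <- crossvalidate(items, mcfg_fn(4, c("acc", "gyro")), tcfg)
  expect_equal(ab$results$kappa[ab$results$subset == "all4"],
               cv$fold_stats$kappa, tolerance = 1e-12)
  # pairwise tests compare cells differing in exactly one axis
  tt <- ablation_tests(ab)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$axis, "subset")
  expect_equal(attr(tt, "n_tests"), 1L)
  tp <- ablation_tests(ab, mode = "pooled")
  expect_equal(nrow(tp), 1L)
})

test_that("ablation serialization round-trips", {
  res <- data.frame(fold = rep(1:3, 2), kappa = runif(6),
                    accuracy = runif(6, 90, 99),
                    subset = rep(c("all4", "one_arm"), each = 3),
                    rate = 52, modality = "acc_gyro")
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(res, p, row.names = FALSE)
  back <- utils::read.csv(p)
  expect_equal(back$kappa, res$kappa)
  expect_equal(back$subset, res$subset)
})
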