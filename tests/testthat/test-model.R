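tiny_cfg <- function(...) {
  args <- list(n_sensors = 2, n_classes = 2, latent_dim = 8,
               enc_filters = c(4, 5), enc_kernels = c(5, 3),
               enc_strides = c(2, 2), n_blocks = 2, dilations = c(1, 2),
               frame_len = 24)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

test_that("model configuration enforces its invariants", {
  expect_error(model_config(4, latent_dim = 0), "latent_dim")
  expect_error(model_config(4, n_classes = 1), "n_classes")
  expect_error(model_config(4, dilations = c(1, 2, 4), n_blocks = 4),
               "one entry per block")
  expect_error(model_config(4, dilations = c(1, 3, 4, 8)), "powers of 2")
  expect_error(model_config(4, active_heads = "magnetometer"), "subset")
})

test_that("the classifier maps frame sequences to normalized probabilities", {
  set.seed(1)
  cfg <- tiny_cfg()
  m <- build_model(cfg)
  X <- array(rnorm(12 * 24 * 30), c(12, 24, 30))
  pr <- predict_frames(m, X)
  expect_equal(dim(pr$prob), c(30, 2))
  expect_equal(rowSums(pr$prob), rep(1, 30), tolerance = 1e-6)
  expect_true(all(pr$label %in% 1:2))
  # deterministic at inference, including across chunk boundaries
  pr2 <- predict_frames(m, X, chunk_len = 7)
  expect_equal(pr2$prob, pr$prob, tolerance = 1e-9)
  # ties break toward the lowest class index
  expect_equal(max.col(matrix(c(0.5, 0.5), 1), ties.method = "first"), 1L)
  expect_error(predict_frames(m, array(0, c(5, 24, 3))), "layout mismatch")
})

test_that("the latent expression has the configured dimension", {
  set.seed(2)
  cfg <- model_config(n_sensors = 4, latent_dim = 160)
  m <- build_model(cfg)
  X <- array(rnorm(24 * 120 * 3), c(24, 120, 3))
  fw <- carrysense:::nn_forward(m$params, cfg, X, keep_cache = TRUE)
  expect_equal(nrow(fw$cache$Zfinal), 160L)
  expect_equal(dim(fw$logits), c(2L, 3L))
})

test_that("an inactive gyroscope head contributes zeros to the fused input", {
  set.seed(3)
  cfg <- tiny_cfg(active_heads = "acc")
  m <- build_model(cfg)
  X <- array(rnorm(6 * 24 * 4), c(6, 24, 4))
  fw <- carrysense:::nn_forward(m$params, cfg, X, keep_cache = TRUE)
  f2 <- cfg$enc_filters[2]
  expect_true(all(fw$cache$fused[f2 + seq_len(f2), ] == 0))
  expect_true(any(fw$cache$fused[seq_len(f2), ] != 0))
})

test_that("compiled convolutions match the pure-R reference implementation", {
  set.seed(12)
  cases <- list(
    list(C = 12, L = 24, B = 7, k = 5, stride = 2, dilation = 1, pad = 0),
    list(C = 8, L = 7, B = 1, k = 3, stride = 1, dilation = 2, pad = 2),
    list(C = 3, L = 30, B = 4, k = 7, stride = 3, dilation = 1, pad = 0)
  )
  for (cs in cases) {
    plan <- carrysense:::conv_plan(cs$L, cs$k, cs$stride, cs$dilation, cs$pad)
    X <- array(rnorm(cs$C * cs$L * cs$B), c(cs$C, cs$L, cs$B))
    W <- matrix(rnorm(6 * cs$C * cs$k), 6)
    b <- rnorm(6)
    for (rl in c(FALSE, TRUE)) {
      Y1 <- carrysense:::conv_fw(X, W, b, plan, relu = rl)
      Y2 <- carrysense:::conv_fw_ref(X, W, b, plan, relu = rl)
      expect_equal(Y1, Y2, tolerance = 1e-12)
      dY <- array(rnorm(length(Y1)), dim(Y1))
      ro <- if (rl) Y1 else NULL
      g1 <- carrysense:::conv_bw(dY, W, X, plan, relu_out = ro)
      g2 <- carrysense:::conv_bw_ref(dY, W, X, plan, relu_out = ro)
      expect_equal(g1$dW, g2$dW, tolerance = 1e-12)
      expect_equal(g1$db, g2$db, tolerance = 1e-12)
      expect_equal(g1$dX, g2$dX, tolerance = 1e-12)
    }
  }
})

test_that("backpropagation matches finite differences", {
  set.seed(42)
  cfg <- tiny_cfg(n_classes = 3)
  m <- build_model(cfg)
  X <- array(rnorm(12 * 24 * 6), c(12, 24, 6))
  y <- c(1L, 2L, NA, 3L, 1L, 2L)
  w <- c(1, 2, 0.5)
  loss_fn <- function(params) {
    carrysense:::softmax_xent(
      carrysense:::nn_forward(params, cfg, X)$logits, y, w)$loss
  }
  fw <- carrysense:::nn_forward(m$params, cfg, X, keep_cache = TRUE)
  sx <- carrysense:::softmax_xent(fw$logits, y, w)
  gr <- carrysense:::nn_backward(m$params, cfg, fw$cache, sx$dlogits)
  eps <- 1e-6
  for (nm in names(gr)) {
    idx <- sample(length(m$params[[nm]]), min(3, length(m$params[[nm]])))
    for (i in idx) {
      pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_lt(abs(num - gr[[nm]][i]) /
                  max(1e-6, abs(num) + abs(gr[[nm]][i])), 1e-3)
    }
  }
})

test_that("class weights are inverse-frequency on valid frames", {
  y <- c(rep(1L, 90), rep(2L, 10), NA, NA)
  w <- class_weights(y, 2)
  expect_equal(w[2] / w[1], 9)
  expect_equal(class_weights(c(1L, 2L, 1L, 2L), 2), c(1, 1))
  expect_error(class_weights(rep(1L, 10), 2), "absent")
  expect_error(class_weights(rep(NA_integer_, 5), 2), "masked")
})

test_that("fold assignment is deterministic, grouped and partitioning", {
  ids <- sprintf("rec%02d", 1:12)
  f1 <- carrysense:::assign_folds(ids, 4, seed = 9)
  f2 <- carrysense:::assign_folds(ids, 4, seed = 9)
  expect_identical(f1, f2)
  expect_equal(sort(unique(f1)), 1:4)
  expect_true(all(table(f1) == 3))
  # grouping by subject keeps a subject's recordings in one fold
  subj <- rep(sprintf("s%d", 1:6), each = 2)
  fs <- carrysense:::assign_folds(ids, 3, seed = 9, subjects = subj)
  expect_true(all(tapply(fs, subj, function(v) length(unique(v))) == 1))
  expect_error(carrysense:::assign_folds(ids[1:3], 4, 1), "at least 4")
})

test_that("training learns a separable task and selects by validation F1", {
  # strongly separable conditions (pronounced shared sway, suppressed limb
  # activity while carried, longer carry dwells): held-out kappa reaches
  # 0.7 within 25 epochs for the majority of seeds
  cfg <- synth_config(duration_s = 480, shared_amp = 3.5, noise_sd = 0.02,
                      dwell_mean_s = c(IM = 26, PS = 4, AS = 3, PC = 10,
                                       AC = 10),
                      limb_gain = c(IM = 1, PS = 0.3, AS = 0.6, PC = 0.02,
                                    AC = 0.05),
                      shared_gain = c(IM = 0, PS = 0.02, AS = 0.8, PC = 0.6,
                                      AC = 1))
  fcfg <- framing_config()
  passes <- 0L
  for (s in 1:3) {
    ds <- synth_dataset(8, cfg, seed = 200 + s, n_annotators = 0)
    items <- prepare_items(ds, scheme = "def2", fcfg = fcfg,
                           use_truth = TRUE)
    mcfg <- model_config(n_sensors = 4, latent_dim = 32,
                         enc_filters = c(8, 16))
    tcfg <- training_config(epochs = 25, learning_rate = 1e-3,
                            seed = s, n_folds = 2,
                            class_weight_power = 0.5)
    m <- train_model(items[1:5], items[6], mcfg, tcfg)
    hist <- m$provenance$history
    # epoch-averaged loss trends down over the first 10 epochs
    expect_lt(mean(hist$train_loss[8:10]), mean(hist$train_loss[1:3]))
    pred <- c(); ref <- c()
    for (i in 7:8) {
      pr <- predict_frames(m, items[[i]]$x)
      pred <- c(pred, pr$label); ref <- c(ref, items[[i]]$y)
    }
    ok <- !is.na(ref)
    k <- kappa_multiclass(confusion(pred[ok], ref[ok], classes = 1:2))
    if (!is.na(k) && k >= 0.7) passes <- passes + 1L
  }
  expect_gte(passes, 2L)
})

test_that("total sensor dropout destroys the signal (sanity property)", {
  cfg <- synth_config(duration_s = 240)
  ds <- synth_dataset(4, cfg, seed = 400, n_annotators = 0)
  items <- prepare_items(ds, scheme = "def2", use_truth = TRUE)
  mcfg <- model_config(n_sensors = 4, latent_dim = 16, enc_filters = c(4, 8))
  tcfg <- training_config(epochs = 4, learning_rate = 1e-3, seed = 1,
                          n_folds = 2, dropout_sensor = 1.0)
  m <- train_model(items[1:3], items[4], mcfg, tcfg)
  pr <- predict_frames(m, items[[4]]$x)
  ok <- !is.na(items[[4]]$y)
  cmt <- table(factor(pr$label[ok], 1:2), factor(items[[4]]$y[ok], 1:2))
  k <- suppressWarnings(kappa_multiclass(as.matrix(cmt)))
  expect_true(is.na(k) || abs(k) < 0.1)
})

test_that("cross-validation partitions recordings and is reproducible", {
  cfg <- synth_config(duration_s = 180)
  ds <- synth_dataset(4, cfg, seed = 77, n_annotators = 0)
  items <- prepare_items(ds, scheme = "def2", use_truth = TRUE)
  mcfg <- model_config(n_sensors = 4, latent_dim = 8, enc_filters = c(3, 4))
  tcfg <- training_config(epochs = 2, learning_rate = 1e-3, seed = 5,
                          n_folds = 4)
  cv <- crossvalidate(items, mcfg, tcfg)
  expect_equal(sort(unique(cv$fold_of_item)), 1:4)
  # pooled predictions cover every recording exactly once, full length
  expect_true(all(!vapply(cv$predictions, is.null, logical(1))))
  expect_equal(unname(vapply(cv$predictions, function(p) length(p$label),
                             integer(1))),
               vapply(items, function(it) dim(it$x)[3], integer(1)))
  cv2 <- crossvalidate(items, mcfg, tcfg)
  expect_identical(cv$fold_of_item, cv2$fold_of_item)
  expect_equal(cv$fold_stats$kappa, cv2$fold_stats$kappa, tolerance = 1e-12)
  expect_error(crossvalidate(items[1:2], mcfg, tcfg), "at least 4")
})
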