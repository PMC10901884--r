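test_that("confusion counts jointly valid frames only", {
  sc <- label_scheme("def2")
  pred <- carrysense:::frame_labels(c(1L, 2L, 2L, NA, 1L), sc)
  ref <- carrysense:::frame_labels(c(1L, 2L, 1L, 1L, NA), sc)
  cm <- confusion(pred, ref)
  expect_equal(sum(cm), 3)
  expect_equal(unname(cm["non_carry", "non_carry"]), 1)
  expect_equal(unname(cm["non_carry", "carry"]), 1)
  all_masked <- carrysense:::frame_labels(rep(NA_integer_, 5), sc)
  expect_error(confusion(all_masked, ref), "no evaluable frames")
})

test_that("binary kappa matches its closed form on hand-computed cases", {
  # perfect, chance and a worked example
  expect_equal(kappa_binary(as_confusion(matrix(c(50, 0, 0, 50), 2, 2),
                                         c("non_carry", "carry"))), 1)
  expect_equal(kappa_binary(as_confusion(matrix(25, 2, 2),
                                         c("non_carry", "carry"))), 0)
  # tp=50 tn=40 fp=5 fn=5: 2*(2000-25)/(55*45 + 55*45)
  cm <- as_confusion(matrix(c(40, 5, 5, 50), 2, 2, byrow = TRUE),
                     c("non_carry", "carry"))
  expect_equal(kappa_binary(cm), 2 * (50 * 40 - 25) / (2 * 55 * 45))
  expect_equal(round(kappa_binary(cm), 3), 0.798)
  expect_warning(kappa_binary(as_confusion(matrix(c(10, 0, 0, 0), 2, 2,
                                                  byrow = TRUE))),
                 "degenerate")
})

test_that("binary and multi-class kappa agree on 1000 random 2x2 matrices", {
  set.seed(42)
  for (i in 1:1000) {
    cm <- matrix(rpois(4, lambda = sample(1:50, 1)) + 1, 2, 2)
    expect_lt(abs(kappa_binary(as_confusion(cm, c("non_carry", "carry"))) -
                    kappa_multiclass(cm)), 1e-12)
  }
})

test_that("kappa matches an independent implementation (e1071)", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 10) + 1, k, k)
    ref <- e1071::classAgreement(cm)$kappa
    expect_equal(kappa_multiclass(cm), ref, tolerance = 1e-12)
  }
})

test_that("kappa is invariant to class permutation and transposition", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    cm <- matrix(rpois(k * k, 8) + 1, k, k)
    p <- sample(k)
    expect_equal(kappa_multiclass(cm[p, p]), kappa_multiclass(cm))
    expect_equal(kappa_multiclass(t(cm)), kappa_multiclass(cm))
    expect_equal(accuracy(cm[p, p]), accuracy(cm))
  }
  expect_warning(kappa_multiclass(matrix(c(5, 0, 0, 0), 2, 2)), "undefined")
})

test_that("precision/recall/F1 reproduce tabulated triples", {
  # printed per-class rows: recall/precision pairs and their F1 (1 d.p.)
  rows <- list(c(recall = 65.4, precision = 42.5, f1 = 51.5),
               c(recall = 56.7, precision = 29.5, f1 = 38.8),
               c(recall = 97.4, precision = 98.8, f1 = 98.1),
               c(recall = 67.5, precision = 39.2, f1 = 49.6),
               c(recall = 76.9, precision = 73.8, f1 = 75.3))
  for (r in rows) {
    expect_lt(abs(f1_score(r["precision"], r["recall"]) - r["f1"]), 0.05)
  }
  # degenerate division yields 0 with a flag
  cm <- as_confusion(matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE),
                     c("non_carry", "carry"))
  out <- prf(cm, "carry")
  expect_equal(out$f1, 0)
  expect_true(out$degenerate)
})

test_that("report averages are proportion-weighted and unweighted", {
  cm <- as_confusion(matrix(c(90, 5, 3, 12), 2, 2, byrow = TRUE),
                     c("non_carry", "carry"))
  rep <- metric_report(cm)
  f1s <- rep$per_class$f1
  expect_equal(rep$unweighted$f1, mean(f1s))
  expect_equal(rep$weighted$f1, sum(rep$per_class$proportion * f1s))
  # two classes with F1 98.1 and 58.2 average to 78.15 unweighted
  expect_equal(mean(c(98.1, 58.2)), 78.15)
  # explicit proportions: all weight on one class
  rep2 <- metric_report(cm, proportions = c(1, 0))
  expect_equal(rep2$weighted$f1, f1s[1])
  expect_error(metric_report(cm, proportions = c(0.6, 0.6)), "sum to 1")
  expect_error(metric_report(cm, proportions = 1), "length")
})

test_that("MCC is available but kappa drives reporting", {
  cm <- as_confusion(matrix(c(40, 5, 5, 50), 2, 2, byrow = TRUE),
                     c("non_carry", "carry"))
  m <- mcc(cm)
  expect_true(m > 0 && m <= 1)
  expect_named(metric_report(cm)["kappa"], "kappa")
})
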