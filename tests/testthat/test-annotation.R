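test_that("tracks are validated, sorted and gap-filled with OOS", {
  tr <- annotation_track(data.frame(start_s = c(20, 0), end_s = c(30, 10),
                                    category = c("PC", "IM")))
  expect_equal(tr$intervals$category, c("IM", "OOS", "PC"))
  expect_equal(tr$intervals$start_s, c(0, 10, 20))

  expect_error(annotation_track(data.frame(start_s = c(0, 5), end_s = c(10, 15),
                                           category = c("IM", "AC"))),
               "overlap at 5.0 s")
  expect_error(annotation_track(data.frame(start_s = 0, end_s = 10,
                                           category = "XX")),
               "unknown category")
  expect_error(annotation_track(data.frame(start_s = 5, end_s = 5,
                                           category = "IM")),
               "end <= start")
})

test_that("annotation CSVs round-trip and report parse errors", {
  tr <- annotation_track(data.frame(start_s = c(0, 10), end_s = c(10, 25),
                                    category = c("IM", "AC")), "a1")
  p <- withr::local_tempfile(fileext = ".csv")
  write_annotations(tr, p)
  tr2 <- load_annotations(p, "a1")
  expect_equal(tr2$intervals, tr$intervals)

  writeLines("start_s,end_s,category\n0,10,IM\n5,15,AC", p)
  expect_error(load_annotations(p), "parse error")
})

test_that("binary definitions collate the five categories per the scheme table", {
  carry_sets <- list(def1 = "AC", def2 = c("PC", "AC"), def3 = c("AS", "AC"),
                     def4 = c("AS", "PC", "AC"),
                     def5 = c("PS", "AS", "PC", "AC"))
  for (nm in names(carry_sets)) {
    sc <- label_scheme(nm)
    expect_identical(sc$classes, c("non_carry", "carry"))
    expect_setequal(names(sc$mapping)[sc$mapping == "carry"], carry_sets[[nm]])
  }
  pa <- label_scheme("passive_active3")
  expect_identical(unname(pa$mapping[c("PS", "PC")]), rep("passive", 2))
  expect_identical(unname(pa$mapping[c("AS", "AC")]), rep("active", 2))
  sc3 <- label_scheme("support_carry3")
  expect_identical(unname(sc3$mapping[c("PC", "AC")]), rep("carry", 2))
  expect_identical(unname(sc3$mapping[c("PS", "AS")]), rep("support", 2))
})

test_that("frame labels follow the majority rule with OOS masking", {
  # frame grid of 2.3 s windows
  times <- cbind(c(0, 5), c(2.3, 7.3))
  # frame 1: 1.4 s AC + 0.9 s IM -> AC -> carry under def2
  tr <- annotation_track(data.frame(start_s = c(0, 1.4, 5, 6.2),
                                    end_s = c(1.4, 5, 6.2, 7.3),
                                    category = c("AC", "IM", "OOS", "IM")))
  fl <- to_frame_labels(tr, times, label_scheme("def2"))
  expect_equal(fl$class_idx[1], 2L)
  # frame 2: 1.2 s OOS + 1.1 s IM -> masked (OOS share >= 50%)
  expect_true(is.na(fl$class_idx[2]))
  expect_false(fl$valid[2])

  # fully-inside frame keeps its category under raw5
  tr2 <- annotation_track(data.frame(start_s = 0, end_s = 10,
                                     category = "PS"))
  fl2 <- to_frame_labels(tr2, times, label_scheme("raw5"))
  expect_equal(label_scheme("raw5")$classes[fl2$class_idx], c("PS", "PS"))
})

test_that("consensus keeps agreement frames and masks the rest", {
  sc <- label_scheme("def2")
  mk <- function(v) carrysense:::frame_labels(v, sc)
  a <- mk(c(1L, 2L, 1L, NA, 2L))
  b <- mk(c(1L, 1L, 1L, 2L, 2L))
  cons <- agreement_mask(a, b)
  expect_equal(cons$class_idx, c(1L, NA, 1L, NA, 2L))
  expect_identical(agreement_mask(a, a)$class_idx, a$class_idx)
  expect_error(agreement_mask(a, mk(c(1L, 1L))), "lengths")
  b5 <- carrysense:::frame_labels(rep(1L, 5), label_scheme("raw5"))
  expect_error(agreement_mask(a, b5), "scheme mismatch")
  # kappa of a track's consensus with itself is exactly 1
  expect_equal(kappa_multiclass(confusion(cons, cons)), 1)
})

test_that("segment lengths merge runs under coarser schemes", {
  tr <- annotation_track(data.frame(start_s = c(0, 10), end_s = c(10, 20),
                                    category = c("PC", "AC")))
  s2 <- segment_lengths(tr, label_scheme("def2"))
  expect_equal(s2$carry, 20)
  s5 <- segment_lengths(tr, label_scheme("raw5"))
  expect_equal(s5$PC, 10)
  expect_equal(s5$AC, 10)
  # coarser schemes never have more segments than raw5
  set.seed(8)
  cfg <- synth_config()
  tr2 <- sample_labels(cfg, seed = 21, duration_s = 900)
  n_raw <- length(unlist(segment_lengths(tr2, label_scheme("raw5"))))
  for (nm in c("def1", "def2", "def5", "support_carry3")) {
    expect_lte(length(unlist(segment_lengths(tr2, label_scheme(nm)))), n_raw)
  }
})
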