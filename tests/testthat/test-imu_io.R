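test_that("recordings validate their structure", {
  expect_error(recording(list()), "non-empty")
  n <- 100
  mk <- function() list(acc = matrix(0, n, 3), gyro = matrix(0, n, 3))
  expect_error(recording(list(head = mk())), "unknown sensor")
  expect_error(recording(list(left_arm = list(acc = matrix(0, 0, 3),
                                              gyro = matrix(0, 0, 3)))),
               "empty recording")
  bad <- list(left_arm = mk(),
              left_leg = list(acc = matrix(0, n + 1, 3),
                              gyro = matrix(0, n + 1, 3)))
  expect_error(recording(bad), "inconsistent")
  expect_error(recording(list(left_arm = mk()), rate_hz = -1), "positive")
})

test_that("a one-hour four-sensor recording has the expected size", {
  # 60 min at 52 Hz: 187,200 samples/channel, 24 channels, 1248 values/s
  cfg <- framing_config()
  expect_equal(60 * 60 * 52, 187200)
  rec <- make_test_recording(n = 520)
  expect_equal(n_channels(rec), 24L)
  expect_equal(n_channels(rec) * rec$rate_hz, 1248)
})

test_that("select_sensors subsets canonically and is idempotent", {
  rec <- make_test_recording(n = 200)
  s <- select_sensors(rec, c("left_leg", "left_arm"))
  expect_identical(s$sensors, c("left_arm", "left_leg"))
  expect_equal(n_channels(s), 12L)
  expect_identical(select_sensors(s, c("left_arm", "left_leg"))$data, s$data)
  expect_identical(s$data$left_arm$acc, rec$data$left_arm$acc)
  s4 <- select_sensors(rec, CH_PLACEMENTS)
  expect_identical(s4$data, rec$data)
  expect_error(select_sensors(rec, character(0)), "non-empty")
  expect_error(select_sensors(rec, "head"), "unknown sensor")
  expect_error(select_sensors(s, "right_arm"), "not present")
})

test_that("file formats round-trip", {
  rec <- make_test_recording(n = 300, sensors = c("left_arm", "left_leg"))
  bin <- withr::local_tempfile(fileext = ".imu")
  write_recording(rec, bin, "binary")
  r2 <- load_recording(bin)
  expect_identical(r2$data, rec$data)        # bit-exact
  expect_equal(r2$rate_hz, rec$rate_hz)
  expect_equal(r2$sensors, rec$sensors)

  txt <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, txt, "delimited", digits = 6)
  r3 <- load_recording(txt)
  expect_lt(max(abs(r3$data$left_leg$acc - rec$data$left_leg$acc)), 1e-6 / 2 + 1e-9)
  expect_equal(r3$sensors, rec$sensors)
})

test_that("the delimited loader names offending fields", {
  p <- withr::local_tempfile()
  writeLines(c("# id=x sensors=left_arm", "0,left_arm,0,0,9.8,0,0,0"), p)
  expect_error(load_recording(p), "rate_hz")
  writeLines(c("# rate_hz=52 id=x sensors=left_arm"), p)
  expect_error(load_recording(p), "empty")
  # timestamp gap > 2 sample periods is rejected, not imputed
  writeLines(c("# rate_hz=52 id=x sensors=left_arm",
               paste0(c(0, 1 / 52, 10), ",left_arm,0,0,9.8,0,0,0",
                      collapse = "\n")), p)
  expect_error(load_recording(p), "gap")
})

test_that("simulate_rate suppresses content above the simulated Nyquist", {
  n <- 3120
  t <- (0:(n - 1)) / 52
  mk <- function(x) list(acc = matrix(x, n, 3), gyro = matrix(0, n, 3))
  rec20 <- recording(list(left_arm = mk(sin(2 * pi * 20 * t))), id = "s")
  out <- simulate_rate(rec20, 13)
  expect_equal(out$n_samples, n)           # grid unchanged
  expect_equal(out$rate_hz, 52)
  expect_lt(sum(out$data$left_arm$acc[, 1]^2) /
              sum(rec20$data$left_arm$acc[, 1]^2), 0.01)
  # DC passes decimation essentially unchanged
  recdc <- recording(list(left_arm = mk(5)), id = "dc")
  for (tg in c(26, 13)) {
    o <- simulate_rate(recdc, tg)
    expect_lt(max(abs(o$data$left_arm$acc - 5)) / 5, 1e-6)
  }
  # in-band content survives
  rec3 <- recording(list(left_arm = mk(sin(2 * pi * 3 * t))), id = "s3")
  o <- simulate_rate(rec3, 26)
  expect_equal(sum(o$data$left_arm$acc[, 1]^2) /
                 sum(rec3$data$left_arm$acc[, 1]^2), 1, tolerance = 0.01)
  # identity at 52, invalid target errors
  expect_identical(simulate_rate(rec3, 52), rec3)
  expect_error(simulate_rate(rec3, 20), "52, 26, 13")
})

test_that("gyro-less recordings are supported but restricted", {
  n <- 200
  rec <- recording(list(left_arm = list(acc = matrix(9.81, n, 3))), id = "a")
  expect_false(rec$has_gyro)
  expect_error(assemble_input(rec, "acc_gyro"), "gyroscope")
  expect_equal(nrow(assemble_input(rec, "acc_raw")$series), 3L)
})
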