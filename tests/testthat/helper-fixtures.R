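# Shared fixtures, all generated in code.

# small multi-sensor recording with reproducible content
make_test_recording <- function(n = 52 * 30, sensors = CH_PLACEMENTS,
                                seed = 1, rate = 52, id = "test") {
  set.seed(seed)
  data <- lapply(sensors, function(s) {
    list(acc = matrix(rnorm(n * 3, sd = 0.3), n, 3) +
           rep(c(0, 0, 9.81), each = n),
         gyro = matrix(rnorm(n * 3, sd = 0.1), n, 3))
  })
  names(data) <- sensors
  recording(data, rate_hz = rate, id = id)
}

# the scaled end-to-end benchmark is shared between the parameter-recovery
# and ablation-ordering acceptance tests; run it once per session
.bench_cache <- new.env(parent = emptyenv())
get_benchmark <- function() {
  if (is.null(.bench_cache$b)) {
    .bench_cache$b <- ch_benchmark(seed = 1)
  }
  .bench_cache$b
}
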