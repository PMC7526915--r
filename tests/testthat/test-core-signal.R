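test_that("impedance_signal validates its inputs", {
  expect_s3_class(impedance_signal(1:5, fs = 250), "ti_signal")
  expect_error(impedance_signal(c(1, NA, 3), fs = 250),
               class = "ccrate_signal_error")
  expect_error(impedance_signal(c(1, Inf), fs = 250),
               class = "ccrate_signal_error")
  expect_error(impedance_signal(numeric(0), fs = 250),
               class = "ccrate_signal_error")
  expect_error(impedance_signal(1:5, fs = 0), class = "ccrate_config_error")
})

test_that("resampling at the native rate is the identity", {
  sig <- sine_signal(0.5, duration_s = 4)
  out <- resample_signal(sig, 250)
  expect_identical(signal_samples(out), signal_samples(sig))
  expect_identical(nrow(out), nrow(sig))
})

test_that("downsampling preserves in-band content", {
  # 2 Hz unit sinusoid at 500 Hz -> 250 Hz; compare against the analytic
  # sinusoid evaluated at the new sample times, away from the edges
  n <- 10 * 500
  sig <- impedance_signal(sin(2 * pi * 2 * (0:(n - 1)) / 500), fs = 500)
  out <- resample_signal(sig, 250)
  expect_identical(nrow(out), 2500L)
  ideal <- sin(2 * pi * 2 * out$time_s)
  interior <- seq(126, 2375)  # drop 0.5 s at each edge
  expect_lt(max(abs(signal_samples(out)[interior] - ideal[interior])), 0.01)
})

test_that("upsampling a constant-zero signal gives zeros of the right length", {
  sig <- impedance_signal(rep(0, 400), fs = 100)
  out <- resample_signal(sig, 250)
  expect_identical(nrow(out), 1000L)
  expect_true(all(signal_samples(out) == 0))
  expect_error(resample_signal(sig, -1), class = "ccrate_config_error")
})

test_that("windows tile the signal and discard the partial tail", {
  cfg <- detector_config()
  w <- segment_windows(impedance_signal(rnorm(2500), fs = 250), cfg)
  expect_identical(nrow(w), 5L)
  expect_equal(w$start_s, c(0, 2, 4, 6, 8))
  expect_equal(w$end_s - w$start_s, rep(2, 5))
  expect_true(all(lengths(w$samples) == 500L))

  w2 <- segment_windows(impedance_signal(rnorm(2475), fs = 250), cfg)  # 9.9 s
  expect_identical(nrow(w2), 4L)

  w3 <- segment_windows(impedance_signal(rnorm(375), fs = 250), cfg)   # 1.5 s
  expect_identical(nrow(w3), 0L)

  # sample conservation: windows + discarded tail = total
  n <- 2475
  expect_identical(sum(lengths(w2$samples)) + (n - 4L * 500L), n)
})

test_that("window preprocessing removes DC and out-of-band power", {
  cfg <- detector_config()
  # constant window is annihilated
  out <- preprocess_window(rep(3, 500), cfg)
  expect_lt(max(abs(out)), 1e-9)

  # 2 Hz kept within 5% amplitude, 30 Hz attenuated below 1% of its power
  t <- (0:499) / 250
  x <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 30 * t)
  y <- preprocess_window(x, cfg)
  expect_lt(abs(mean(y)), 1e-9)
  spec_power <- function(v, f_hz) {
    ft <- fft(v)
    bin <- round(f_hz * length(v) / 250) + 1
    Mod(ft[bin])^2
  }
  expect_lt(spec_power(y, 30) / spec_power(x, 30), 0.01)
  expect_lt(abs(sqrt(spec_power(y, 2) / spec_power(x, 2)) - 1), 0.05)

  # filtering removes energy from white noise
  set.seed(4)
  wn <- rnorm(500)
  expect_lt(var(preprocess_window(wn, cfg)), var(wn))
})

test_that("window preprocessing is linear", {
  cfg <- detector_config()
  set.seed(8)
  x <- rnorm(500); y <- rnorm(500)
  lhs <- preprocess_window(2.5 * x - 1.3 * y, cfg)
  rhs <- 2.5 * preprocess_window(x, cfg) - 1.3 * preprocess_window(y, cfg)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("resample + segment is deterministic", {
  set.seed(12)
  x <- rnorm(3000)
  sig <- impedance_signal(x, fs = 300)
  a <- segment_windows(resample_signal(sig, 250), detector_config())
  b <- segment_windows(resample_signal(impedance_signal(x, fs = 300), 250),
                       detector_config())
  expect_identical(a, b)
})
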