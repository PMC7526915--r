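test_that("a continuous 110 cpm episode realizes rate x duration compressions", {
  scn <- episode_scenario(duration_s = 120, rate_cpm_mean = 110,
                          rate_cpm_jitter_sd = 0, ccf_target = 1,
                          ventilation_amp_ohm = 0, drift_amp_ohm = 0,
                          noise_sd_ohm = 0, seed = 7)
  ep <- generate_episode(scn)
  expect_identical(length(ep$annotation$instances_s), 220L)
  refs <- label_windows(ep$annotation, detect_compressions(ep$signal))
  expect_true(all(refs$label == "compressions"))
})

test_that("realized windowed CCF tracks the target", {
  scn <- episode_scenario(duration_s = 600, ccf_target = 0.68, seed = 1)
  ep <- generate_episode(scn)
  grid <- segment_windows(ep$signal, detector_config())
  refs <- label_windows(ep$annotation, grid)
  ccf <- mean(refs$label == "compressions")
  expect_gte(ccf, 0.63)
  expect_lte(ccf, 0.73)
})

test_that("generation is bit-deterministic in the seed", {
  scn <- episode_scenario(duration_s = 45, seed = 99)
  a <- generate_episode(scn)
  b <- generate_episode(scn)
  expect_identical(signal_samples(a$signal), signal_samples(b$signal))
  expect_identical(a$annotation$instances_s, b$annotation$instances_s)
  c_ <- generate_episode(episode_scenario(duration_s = 45, seed = 100))
  expect_false(identical(signal_samples(a$signal), signal_samples(c_$signal)))
})

test_that("annotated instants sit on crests of the noiseless waveform", {
  scn <- episode_scenario(duration_s = 60, rate_cpm_mean = 140,
                          ventilation_amp_ohm = 0, drift_amp_ohm = 0,
                          noise_sd_ohm = 0, seed = 3)
  ep <- generate_episode(scn)
  x <- signal_samples(ep$signal)
  for (t in ep$annotation$instances_s) {
    i <- round(t * 250) + 1
    win <- max(1, i - 2):min(length(x), i + 2)
    # the instant is within one sample of a local maximum
    expect_lte(max(x[win]) - max(x[max(1, i - 1):min(length(x), i + 1)]), 1e-9)
  }
})

test_that("zero fluctuation amplitude yields annotation without signal", {
  scn <- episode_scenario(duration_s = 60, fluctuation_amp_ohm = 0,
                          ventilation_amp_ohm = 0, drift_amp_ohm = 0,
                          seed = 11)
  ep <- generate_episode(scn)
  expect_gt(length(ep$annotation$instances_s), 0)
  # signal is pure noise at the configured SD
  expect_lt(abs(sd(signal_samples(ep$signal)) - scn$noise_sd_ohm), 0.02)
})

test_that("infeasible scenarios are rejected with a named constraint", {
  expect_error(episode_scenario(duration_s = 1, rate_cpm_mean = 60,
                                ccf_target = 0.1),
               class = "ccrate_scenario_error")
  expect_error(episode_scenario(ccf_target = 1.2),
               class = "ccrate_scenario_error")
  expect_error(episode_scenario(rate_cpm_mean = 500),
               class = "ccrate_scenario_error")
  expect_error(episode_scenario(noise_sd_ohm = -1),
               class = "ccrate_scenario_error")
})

test_that("benchmark collections are reproducible and match the field rate distribution", {
  a <- generate_benchmark(3, master_seed = 42, duration_s = 20)
  b <- generate_benchmark(3, master_seed = 42, duration_s = 20)
  expect_identical(purrr::map(a$signal, signal_samples),
                   purrr::map(b$signal, signal_samples))

  big <- generate_benchmark(50, master_seed = 42, duration_s = 20)
  med <- median(big$rate_cpm_mean)
  expect_gte(med, 157)
  expect_lte(med, 190)
  expect_true(all(big$rate_cpm_mean >= 60 & big$rate_cpm_mean <= 250))
})

test_that("a degenerate rate distribution recovers its rate in the annotation", {
  one <- generate_benchmark(1, master_seed = 9, duration_s = 60,
                            rate_sd_cpm = 0, rate_mean_cpm = 100,
                            ccf_target = 1)
  ins <- one$annotation[[1]]$instances_s
  mean_rate <- 60 * (length(ins) - 1) / (ins[length(ins)] - ins[1])
  expect_lt(abs(mean_rate - 100), 2)
})

test_that("ground-truth closure: reference metrics recover scenario parameters", {
  scn <- episode_scenario(duration_s = 120, rate_cpm_mean = 120,
                          ccf_target = 0.7, seed = 21)
  ep <- generate_episode(scn)
  grid <- segment_windows(ep$signal, detector_config())
  refs <- label_windows(ep$annotation, grid)
  rr <- refs$reference_rate_cpm[!is.na(refs$reference_rate_cpm)]
  expect_lt(abs(median(rr) - 120), 5)  # within jitter-predicted tolerance
  expect_lt(abs(mean(refs$label == "compressions") - 0.7), 0.05)
})
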