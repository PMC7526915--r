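mk_windows <- function(n, len = 2) {
  tibble::tibble(window_index = 0:(n - 1), start_s = (0:(n - 1)) * len,
                 end_s = (1:n) * len)
}

test_that("window labeling follows the overlap rule and the printed rate definition", {
  ann <- episode_annotation(data.frame(start_s = 0, end_s = 10),
                            instances_s = c(0.25, 0.75, 1.25, 1.75, 3, 5, 7, 9))
  refs <- label_windows(ann, mk_windows(1))
  expect_identical(refs$label, "compressions")
  expect_equal(refs$reference_rate_cpm, 60 * 3 / 1.5)  # 120 cpm

  # zero overlap
  ann2 <- episode_annotation(data.frame(start_s = 10, end_s = 20),
                             instances_s = c(12, 13))
  refs2 <- label_windows(ann2, mk_windows(1))
  expect_identical(refs2$label, "no_compressions")
  expect_true(is.na(refs2$reference_rate_cpm))

  # 0.8 s of 2.0 s = 40% overlap -> below the 50% rule
  ann3 <- episode_annotation(data.frame(start_s = 1.2, end_s = 10),
                             instances_s = c(2, 3))
  refs3 <- label_windows(ann3, mk_windows(1))
  expect_identical(refs3$label, "no_compressions")

  # a single in-window instant defines no reference rate
  ann4 <- episode_annotation(data.frame(start_s = 0, end_s = 10),
                             instances_s = c(1, 3, 5))
  refs4 <- label_windows(ann4, mk_windows(1))
  expect_identical(refs4$label, "compressions")
  expect_true(is.na(refs4$reference_rate_cpm))
})

test_that("windows overlapping an excluded interval are dropped from the grid", {
  ann <- episode_annotation(data.frame(start_s = 0, end_s = 10),
                            instances_s = seq(0.5, 9.5, 0.5),
                            excluded = data.frame(start_s = 2.5, end_s = 3.5))
  refs <- label_windows(ann, mk_windows(5))
  expect_identical(nrow(refs), 4L)
  expect_false(1L %in% refs$window_index)  # window [2,4) overlaps the mask
})

test_that("confusion counts follow the four printed categories", {
  res <- tibble::tibble(window_index = 0:4,
                        detected = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                        rate_cpm = c(110, 115, 100, 0, 0))
  ref <- tibble::tibble(window_index = 0:4,
                        label = c(rep("compressions", 3),
                                  rep("no_compressions", 2)))
  cnt <- confusion(res, ref)
  expect_identical(unlist(cnt), c(TP = 3L, TN = 2L, FP = 0L, FN = 0L))

  # a detection in a no-compressions window is a false positive
  cnt2 <- confusion(
    tibble::tibble(window_index = 0L, detected = TRUE, rate_cpm = 120),
    tibble::tibble(window_index = 0L, label = "no_compressions"))
  expect_identical(cnt2$FP, 1L)

  # empty input gives all-zero counts
  cnt3 <- confusion(tibble::tibble(window_index = integer(),
                                   detected = logical(), rate_cpm = numeric()),
                    tibble::tibble(window_index = integer(), label = character()))
  expect_true(all(unlist(cnt3) == 0))

  expect_error(confusion(
    tibble::tibble(window_index = c(0L, 0L), detected = c(TRUE, TRUE)),
    tibble::tibble(window_index = 0L, label = "compressions")),
    class = "ccrate_contract_error")
})

test_that("figures of merit use the printed ratios and keep zero denominators undefined", {
  f <- figures_of_merit(tibble::tibble(TP = 9, TN = 0, FP = 0, FN = 1))
  expect_equal(f$Se, 90)

  f2 <- figures_of_merit(tibble::tibble(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(is.na(f2$PPV))
  expect_false(is.na(f2$Sp))

  f3 <- figures_of_merit(tibble::tibble(TP = 987, TN = 435, FP = 13, FN = 13))
  expect_equal(f3$Se, 98.7)
  expect_equal(f3$PPV, 98.7)
})

test_that("per-episode summaries use the normal-approximation interval", {
  s <- per_episode_summary(c(98, 100, 96, 100, 98))
  expect_equal(s$mean, 98.4)
  expect_equal(s$ci_low, 98.4 - 1.96 * sd(c(98, 100, 96, 100, 98)) / sqrt(5),
               tolerance = 1e-12)
  expect_equal(round(c(s$ci_low, s$ci_high), 2), c(96.93, 99.87))

  same <- per_episode_summary(rep(97, 4))
  expect_equal(same$ci_high - same$ci_low, 0)

  one <- per_episode_summary(c(95, NA))
  expect_equal(one$mean, 95)
  expect_true(is.na(one$ci_low))
})

test_that("rate errors are signed reference minus estimate over rated TP windows", {
  res <- tibble::tibble(window_index = 0:2,
                        detected = c(TRUE, TRUE, FALSE),
                        rate_cpm = c(118, 140, 0))
  ref <- tibble::tibble(window_index = 0:2,
                        label = c("compressions", "no_compressions", "compressions"),
                        reference_rate_cpm = c(120, NA, 100))
  re <- rate_error(res, ref)
  expect_identical(nrow(re$windows), 1L)       # FP and FN contribute nothing
  expect_equal(re$windows$error_cpm, 2)
  expect_equal(re$median_abs_error_cpm, 2)
  expect_equal(re$frac_within_10cpm, 1)
})

test_that("CCF metrics follow the window-share definitions", {
  res <- tibble::tibble(window_index = 0:29,
                        detected = c(rep(TRUE, 21), rep(FALSE, 9)),
                        rate_cpm = c(rep(110, 21), rep(0, 9)))
  ref <- tibble::tibble(window_index = 0:29,
                        label = c(rep("compressions", 20),
                                  rep("no_compressions", 10)))
  m <- ccf_metrics(res, ref)
  expect_equal(m$ccf_reference_pct, 100 * 20 / 30)
  expect_equal(m$ccf_estimated_pct, 70)
  expect_equal(m$ccf_error_pct, 100 * 21 / 30 - 100 * 20 / 30)
})

test_that("evaluation is additive over episodes and invariant to their order", {
  bench <- run_corpus(generate_benchmark(3, master_seed = 31, duration_s = 30))
  rep_a <- evaluate_corpus(bench)
  rep_b <- evaluate_corpus(bench[c(3, 1, 2), ])
  expect_equal(rep_a$global$counts$TP, sum(rep_a$per_episode$TP))
  expect_equal(rep_a$global$metrics, rep_b$global$metrics)
  expect_equal(sort(rep_a$per_episode$Se), sort(rep_b$per_episode$Se))

  single <- evaluate_corpus(bench[1, ])
  expect_equal(single$global$metrics$Se, single$per_episode$Se[1])
})

test_that("complementarity: counts partition the evaluated windows", {
  bench <- run_corpus(generate_benchmark(2, master_seed = 77, duration_s = 30))
  for (i in 1:2) {
    cnt <- confusion(bench$results[[i]], bench$references[[i]])
    labs <- bench$references[[i]]$label
    expect_identical(cnt$TP + cnt$FN, sum(labs == "compressions"))
    expect_identical(cnt$TN + cnt$FP, sum(labs == "no_compressions"))
  }
})

test_that("tidy and glance expose the report in broom layout", {
  bench <- run_corpus(generate_benchmark(2, master_seed = 13, duration_s = 30))
  rep <- evaluate_corpus(bench)
  td <- tidy(rep)
  expect_true(all(c("term", "scope", "estimate") %in% names(td)))
  expect_identical(nrow(td[td$scope == "global", ]), 4L)
  gl <- glance(rep)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_episodes, 2L)
  expect_error(evaluate_corpus(data.frame()), class = "ccrate_contract_error")
})
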