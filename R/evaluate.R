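#' Label analysis windows from an annotation
#'
#' Converts interval ground truth into the per-window reference the
#' evaluation protocol scores against. A window is labelled `compressions`
#' when its overlap with the union of annotated compression series covers at
#' least `overlap_fraction` of the window (default one half, a symmetric,
#' parameter-free reading of "a window with annotated chest compressions").
#' The reference compression rate of a window is defined from the annotated
#' instants that fall inside it — the inverse of their mean spacing,
#' `60 * (n - 1) / (t_last - t_first)` cpm — and only when the window holds at
#' least two instants. Windows overlapping an excluded interval (shock,
#' pad disconnection) are dropped from the grid.
#'
#' @param annotation A [episode_annotation()].
#' @param windows A data frame with columns `window_index`, `start_s`,
#'   `end_s` — the grid from [segment_windows()] or the output of
#'   [detect_compressions()].
#' @param overlap_fraction Minimum fractional overlap with annotated series
#'   for a `compressions` label.
#' @return A tibble: `window_index`, `label` (`"compressions"` /
#'   `"no_compressions"`), `reference_rate_cpm` (`NA` when undefined).
#' @export
label_windows <- function(annotation, windows, overlap_fraction = 0.5) {
  stopifnot(inherits(annotation, "cc_annotation"))
  req <- c("window_index", "start_s", "end_s")
  if (!all(req %in% names(windows))) {
    abort("`windows` needs columns window_index, start_s, end_s.",
          class = "ccrate_contract_error")
  }
  ser <- annotation$series
  exc <- annotation$excluded
  ins <- annotation$instances_s
  out <- purrr::pmap_dfr(
    windows[, req],
    function(window_index, start_s, end_s) {
      len <- end_s - start_s
      if (nrow(exc) &&
          any(pmin(end_s, exc$end_s) - pmax(start_s, exc$start_s) > 0)) {
        return(tibble(window_index = integer(), label = character(),
                      reference_rate_cpm = numeric()))
      }
      ov <- if (nrow(ser)) {
        sum(pmax(0, pmin(end_s, ser$end_s) - pmax(start_s, ser$start_s)))
      } else 0
      lab <- if (ov >= overlap_fraction * len) "compressions" else "no_compressions"
      inw <- ins[ins >= start_s & ins < end_s]
      ref <- if (length(inw) >= 2) {
        60 * (length(inw) - 1) / (inw[length(inw)] - inw[1])
      } else NA_real_
      tibble(window_index = as.integer(window_index), label = lab,
             reference_rate_cpm = ref)
    }
  )
  out
}

#' Window-level confusion counts
#'
#' Classifies each evaluated window into one of the four categories of the
#' detection protocol: TP, a non-zero rate reported for a window with
#' annotated compressions; TN, a zero reported for a window without; FP, a
#' non-zero rate for a window without compressions; FN, a zero for a window
#' with compressions.
#'
#' @param results Detector output with columns `window_index`, `detected`
#'   (from [detect_compressions()]).
#' @param references Window references with columns `window_index`, `label`
#'   (from [label_windows()]). Windows present in only one of the two tables
#'   (e.g. excluded ones) are not scored.
#' @return A one-row tibble with integer columns `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(results, references) {
  if (!all(c("window_index", "detected") %in% names(results)) ||
      !all(c("window_index", "label") %in% names(references))) {
    abort("`results` needs window_index/detected; `references` needs window_index/label.",
          class = "ccrate_contract_error")
  }
  if (anyDuplicated(results$window_index) ||
      anyDuplicated(references$window_index)) {
    abort("Window indices must be unique.", class = "ccrate_contract_error")
  }
  j <- dplyr::inner_join(results[, c("window_index", "detected")],
                         references[, c("window_index", "label")],
                         by = "window_index")
  pos <- j$label == "compressions"
  tibble(
    TP = sum(j$detected & pos),
    TN = sum(!j$detected & !pos),
    FP = sum(j$detected & !pos),
    FN = sum(!j$detected & pos)
  )
}

#' Detection figures of merit
#'
#' Sensitivity `100 TP / (TP + FN)`, positive predictive value
#' `100 TP / (TP + FP)`, specificity `100 TN / (TN + FP)` and negative
#' predictive value `100 TN / (TN + FN)`, each in percent. A figure whose
#' denominator is zero is undefined and reported as `NA` — never as 0 or 100.
#'
#' @param counts A one-row data frame with columns `TP`, `TN`, `FP`, `FN`.
#' @return A one-row tibble with columns `Se`, `PPV`, `Sp`, `NPV` (percent).
#' @examples
#' figures_of_merit(tibble::tibble(TP = 9, TN = 0, FP = 0, FN = 1))
#' @export
figures_of_merit <- function(counts) {
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(counts, tibble(
    Se = ratio(TP, TP + FN),
    PPV = ratio(TP, TP + FP),
    Sp = ratio(TN, TN + FP),
    NPV = ratio(TN, TN + FN)
  ))
}

#' Mean and normal-approximation 95% confidence interval
#'
#' Summarizes a per-episode metric across episodes: the mean over episodes
#' with a defined value, and the interval `mean ± 1.96 sd / sqrt(n)`. With a
#' single defined value the mean is reported without an interval.
#'
#' @param values Numeric vector of per-episode metric values; `NA`s
#'   (undefined episodes) are dropped.
#' @return A one-row tibble: `mean`, `ci_low`, `ci_high`, `n`.
#' @examples
#' per_episode_summary(c(98, 100, 96, 100, 98))
#' @export
per_episode_summary <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  if (n == 0) {
    return(tibble(mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_, n = 0L))
  }
  m <- mean(v)
  if (n < 2) {
    return(tibble(mean = m, ci_low = NA_real_, ci_high = NA_real_, n = n))
  }
  half <- 1.96 * sd(v) / sqrt(n)
  tibble(mean = m, ci_low = m - half, ci_high = m + half, n = as.integer(n))
}

#' Compression-rate estimation error
#'
#' The error sample of a window is the reference rate minus the algorithm's
#' estimate. Only true-positive windows with a defined reference rate (at
#' least two annotated instants in the window) contribute; false positives
#' and windows with a single instant contribute nothing.
#'
#' @inheritParams confusion
#' @return A list with `windows` (tibble: `window_index`,
#'   `reference_rate_cpm`, `rate_cpm`, `error_cpm` signed as reference minus
#'   estimate), `median_abs_error_cpm`, `iqr_abs_error_cpm` (linear-interpolation
#'   quartiles), `frac_within_10cpm` (share of contributing windows with
#'   absolute error at or below 10 cpm) and `n_ref_above_range` (windows whose
#'   annotated rate exceeds 250 cpm, outside the detector's design range).
#' @export
rate_error <- function(results, references) {
  j <- dplyr::inner_join(
    results[, c("window_index", "detected", "rate_cpm")],
    references[, c("window_index", "label", "reference_rate_cpm")],
    by = "window_index"
  )
  tp <- j$detected & j$label == "compressions" & !is.na(j$reference_rate_cpm)
  w <- tibble(
    window_index = j$window_index[tp],
    reference_rate_cpm = j$reference_rate_cpm[tp],
    rate_cpm = j$rate_cpm[tp],
    error_cpm = j$reference_rate_cpm[tp] - j$rate_cpm[tp]
  )
  abs_err <- abs(w$error_cpm)
  list(
    windows = w,
    median_abs_error_cpm = if (nrow(w)) median(abs_err) else NA_real_,
    iqr_abs_error_cpm = if (nrow(w)) {
      unname(quantile(abs_err, c(0.25, 0.75), type = 7))
    } else c(NA_real_, NA_real_),
    frac_within_10cpm = if (nrow(w)) mean(abs_err <= 10) else NA_real_,
    n_ref_above_range = sum(j$reference_rate_cpm > 250, na.rm = TRUE)
  )
}

#' Chest compression fraction metrics
#'
#' The reference CCF of an episode is the percentage of its 2-s windows with
#' annotated chest compressions; the algorithm's estimate is the percentage
#' of windows in which it detected compressions. Their absolute difference is
#' the CCF estimation error.
#'
#' @inheritParams confusion
#' @return A one-row tibble: `ccf_reference_pct`, `ccf_estimated_pct`,
#'   `ccf_error_pct`.
#' @export
ccf_metrics <- function(results, references) {
  j <- dplyr::inner_join(results[, c("window_index", "detected")],
                         references[, c("window_index", "label")],
                         by = "window_index")
  if (nrow(j) == 0) {
    abort("No aligned windows to evaluate.", class = "ccrate_contract_error")
  }
  ref <- 100 * mean(j$label == "compressions")
  est <- 100 * mean(j$detected)
  tibble(ccf_reference_pct = ref, ccf_estimated_pct = est,
         ccf_error_pct = abs(ref - est))
}

#' Evaluate one episode
#'
#' Convenience wrapper computing confusion counts, figures of merit, rate
#' error and CCF metrics for a single episode.
#'
#' @inheritParams confusion
#' @return A list: `counts`, `metrics`, `rate_error`, `ccf`.
#' @export
evaluate_episode <- function(results, references) {
  counts <- confusion(results, references)
  list(
    counts = counts,
    metrics = figures_of_merit(counts),
    rate_error = rate_error(results, references),
    ccf = ccf_metrics(results, references)
  )
}

#' Evaluate a corpus of episodes
#'
#' Applies the full evaluation protocol to a collection of episodes. Global
#' figures of merit pool all windows of all episodes; per-episode figures are
#' computed independently and summarized as mean with a 95% confidence
#' interval across episodes. Rate-error and CCF-error distributions are
#' summarized as median (IQR) with linear-interpolation quantiles.
#'
#' @param corpus A data frame with list columns `results` (detector outputs)
#'   and `references` (window references), one row per episode, plus an
#'   optional `episode` identifier column.
#' @return An object of class `cc_evaluation`; see [tidy.cc_evaluation()],
#'   [glance.cc_evaluation()] and `print()`.
#' @examples
#' bench <- generate_benchmark(2, master_seed = 1, duration_s = 30)
#' corpus <- dplyr::mutate(bench,
#'   results = purrr::map(signal, detect_compressions),
#'   references = purrr::map2(annotation, results, label_windows)
#' )
#' evaluate_corpus(corpus)
#' @export
evaluate_corpus <- function(corpus) {
  if (!is.data.frame(corpus) || nrow(corpus) == 0 ||
      !all(c("results", "references") %in% names(corpus))) {
    abort("`corpus` must be a non-empty data frame with list columns `results` and `references`.",
          class = "ccrate_contract_error")
  }
  ids <- if ("episode" %in% names(corpus)) corpus$episode else seq_len(nrow(corpus))
  per <- purrr::map2_dfr(corpus$results, corpus$references, function(res, ref) {
    ev <- evaluate_episode(res, ref)
    dplyr::bind_cols(
      ev$counts, ev$metrics,
      tibble(
        median_abs_rate_error_cpm = ev$rate_error$median_abs_error_cpm,
        n_rate_windows = nrow(ev$rate_error$windows),
        n_ref_above_range = ev$rate_error$n_ref_above_range
      ),
      ev$ccf
    )
  })
  per <- dplyr::bind_cols(tibble(episode = ids), per)
  totals <- tibble(TP = sum(per$TP), TN = sum(per$TN),
                   FP = sum(per$FP), FN = sum(per$FN))
  pooled_err <- dplyr::bind_rows(
    purrr::map2(corpus$results, corpus$references,
                function(res, ref) rate_error(res, ref)$windows)
  )
  summarize_med <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      return(tibble(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
    }
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
    tibble(median = unname(q[2]), q25 = unname(q[1]), q75 = unname(q[3]))
  }
  out <- list(
    n_episodes = nrow(per),
    n_windows = sum(totals),
    global = list(counts = totals, metrics = figures_of_merit(totals)),
    per_episode = per,
    per_episode_ci = purrr::map_dfr(
      c("Se", "PPV", "Sp", "NPV"),
      function(mname) {
        dplyr::bind_cols(tibble(metric = mname),
                         per_episode_summary(per[[mname]]))
      }
    ),
    rate_error = list(
      per_episode_median = summarize_med(per$median_abs_rate_error_cpm),
      pooled_frac_within_10cpm = if (nrow(pooled_err)) {
        mean(abs(pooled_err$error_cpm) <= 10)
      } else NA_real_,
      n_windows = nrow(pooled_err)
    ),
    ccf = list(
      error = summarize_med(per$ccf_error_pct),
      reference = summarize_med(per$ccf_reference_pct),
      estimated = summarize_med(per$ccf_estimated_pct)
    ),
    n_ref_above_range = sum(per$n_ref_above_range)
  )
  class(out) <- "cc_evaluation"
  out
}
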