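#' @export
print.cc_evaluation <- function(x, ...) {
  cat(sprintf("<cc_evaluation> %d episodes, %d windows\n",
              x$n_episodes, x$n_windows))
  g <- x$global$metrics
  cat(sprintf("  global: Se %s  PPV %s  Sp %s  NPV %s\n",
              fmt_pct(g$Se), fmt_pct(g$PPV), fmt_pct(g$Sp), fmt_pct(g$NPV)))
  re <- x$rate_error$per_episode_median
  cat(sprintf("  rate error (per-episode median |err|): %s (%s-%s) cpm\n",
              fmt_num(re$median), fmt_num(re$q25), fmt_num(re$q75)))
  ce <- x$ccf$error
  cat(sprintf("  CCF error: %s (%s-%s) %%\n",
              fmt_num(ce$median), fmt_num(ce$q25), fmt_num(ce$q75)))
  invisible(x)
}

fmt_pct <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f%%", v)
fmt_num <- function(v) if (is.na(v)) "n/a" else sprintf("%.1f", v)

#' Tidy an evaluation report
#'
#' Returns one row per figure of merit at global and per-episode scope, with
#' confidence bounds where defined, in the usual broom layout.
#'
#' @param x A `cc_evaluation` from [evaluate_corpus()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `scope`, `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
tidy.cc_evaluation <- function(x, ...) {
  g <- x$global$metrics
  global <- tibble(
    term = c("Se", "PPV", "Sp", "NPV"),
    scope = "global",
    estimate = c(g$Se, g$PPV, g$Sp, g$NPV),
    conf.low = NA_real_,
    conf.high = NA_real_
  )
  per <- tibble(
    term = x$per_episode_ci$metric,
    scope = "per_episode",
    estimate = x$per_episode_ci$mean,
    conf.low = x$per_episode_ci$ci_low,
    conf.high = x$per_episode_ci$ci_high
  )
  extra <- tibble(
    term = c("median_abs_rate_error_cpm", "ccf_error_pct"),
    scope = "per_episode",
    estimate = c(x$rate_error$per_episode_median$median, x$ccf$error$median),
    conf.low = c(x$rate_error$per_episode_median$q25, x$ccf$error$q25),
    conf.high = c(x$rate_error$per_episode_median$q75, x$ccf$error$q75)
  )
  dplyr::bind_rows(global, per, extra)
}

#' One-row summary of an evaluation report
#'
#' @param x A `cc_evaluation` from [evaluate_corpus()].
#' @param ... Unused.
#' @return A one-row tibble with the pooled confusion counts, global figures
#'   of merit, rate-error and CCF-error medians.
#' @export
glance.cc_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    x$global$counts,
    x$global$metrics,
    tibble(
      median_abs_rate_error_cpm = x$rate_error$per_episode_median$median,
      frac_within_10cpm = x$rate_error$pooled_frac_within_10cpm,
      ccf_error_pct = x$ccf$error$median,
      n_episodes = x$n_episodes,
      n_windows = x$n_windows,
      n_ref_above_range = x$n_ref_above_range
    )
  )
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `cc_evaluation` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cc_evaluation"))
  payload <- unclass(report)
  jsonlite::write_json(payload, path, digits = NA, dataframe = "columns",
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an evaluation report written by [write_report_json()]
#'
#' @param path Path to the report JSON.
#' @return A `cc_evaluation` object.
#' @export
read_report_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Report file not found: %s", path), class = "ccrate_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("n_episodes", "n_windows", "global", "per_episode", "rate_error", "ccf")
  if (!all(need %in% names(raw))) {
    abort("File does not look like a ccrate evaluation report.",
          class = "ccrate_io_error")
  }
  raw$global$counts <- as_tibble(raw$global$counts)
  raw$global$metrics <- as_tibble(lapply(raw$global$metrics,
                                         function(v) v %||% NA_real_))
  raw$per_episode <- as_tibble(raw$per_episode)
  raw$per_episode_ci <- as_tibble(raw$per_episode_ci)
  structure(raw, class = "cc_evaluation")
}

#' Render an evaluation report as text
#'
#' Produces the human-readable summary printed by the `report` command: the
#' global figures of merit, per-episode means with confidence intervals, the
#' rate-error and CCF-error medians with IQRs, and one table row per episode.
#'
#' @param report A `cc_evaluation` object.
#' @return A character vector of lines.
#' @export
report_text <- function(report) {
  stopifnot(inherits(report, "cc_evaluation"))
  g <- report$global$metrics
  ci <- report$per_episode_ci
  fmt_ci <- function(row) {
    if (is.na(row$mean)) return("n/a")
    if (is.na(row$ci_low)) return(sprintf("%.1f%% (CI n/a)", row$mean))
    sprintf("%.1f%% (95%% CI: %.1f-%.1f)", row$mean, row$ci_low, row$ci_high)
  }
  lines <- c(
    sprintf("Evaluation of %d episode(s), %d analysis windows",
            report$n_episodes, report$n_windows),
    "",
    sprintf("Global:      Se %s  PPV %s  Sp %s  NPV %s",
            fmt_pct(g$Se), fmt_pct(g$PPV), fmt_pct(g$Sp), fmt_pct(g$NPV)),
    "Per episode:"
  )
  for (i in seq_len(nrow(ci))) {
    lines <- c(lines, sprintf("  %-4s %s", ci$metric[i], fmt_ci(ci[i, ])))
  }
  re <- report$rate_error$per_episode_median
  ce <- report$ccf$error
  lines <- c(
    lines,
    sprintf("Rate error:  median %s (IQR %s-%s) cpm over %d windows",
            fmt_num(re$median), fmt_num(re$q25), fmt_num(re$q75),
            report$rate_error$n_windows),
    sprintf("             |error| <= 10 cpm in %s of rated windows",
            if (is.na(report$rate_error$pooled_frac_within_10cpm)) "n/a"
            else sprintf("%.1f%%", 100 * report$rate_error$pooled_frac_within_10cpm)),
    sprintf("CCF error:   median %s (IQR %s-%s) %%",
            fmt_num(ce$median), fmt_num(ce$q25), fmt_num(ce$q75))
  )
  if (isTRUE(report$n_ref_above_range > 0)) {
    lines <- c(lines, sprintf(
      "Note: %d window(s) had annotated rates above the 250 cpm design range.",
      report$n_ref_above_range))
  }
  pe <- report$per_episode
  lines <- c(lines, "", "Per-episode table:",
             sprintf("  %-8s %4s %4s %4s %4s %6s %6s %6s %6s %8s %7s",
                     "episode", "TP", "TN", "FP", "FN",
                     "Se", "PPV", "Sp", "NPV", "rate_err", "ccf_err"))
  for (i in seq_len(nrow(pe))) {
    p <- pe[i, ]
    lines <- c(lines, sprintf(
      "  %-8s %4d %4d %4d %4d %6s %6s %6s %6s %8s %7s",
      as.character(p$episode), p$TP, p$TN, p$FP, p$FN,
      fmt_num(p$Se), fmt_num(p$PPV), fmt_num(p$Sp), fmt_num(p$NPV),
      fmt_num(p$median_abs_rate_error_cpm), fmt_num(p$ccf_error_pct)))
  }
  lines
}
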