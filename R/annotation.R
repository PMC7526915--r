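#' Ground-truth annotation of a resuscitation episode
#'
#' Holds the reference standard against which the detector is scored: the
#' beginning and end of each chest compression series, the time of each
#' individual compression, and (optionally) time intervals excluded from
#' analysis (shock artifacts, pad disconnections).
#'
#' @param series A data frame with columns `start_s`, `end_s`: non-overlapping,
#'   time-ordered compression-series intervals.
#' @param instances_s Numeric vector of individual compression instants in
#'   seconds; every instant must fall inside a series and consecutive instants
#'   within a series must be more than 0.2 s apart (300 cpm, the fastest
#'   plausible compression rate).
#' @param excluded Optional data frame with columns `start_s`, `end_s` of
#'   intervals to drop from evaluation.
#'
#' @return An object of class `cc_annotation`: a list with tibbles `series`
#'   and `excluded`, and the numeric vector `instances_s`.
#' @examples
#' ann <- episode_annotation(
#'   series = data.frame(start_s = 0, end_s = 10),
#'   instances_s = seq(0.5, 9.5, by = 0.5)
#' )
#' ann
#' @export
episode_annotation <- function(series, instances_s = numeric(),
                               excluded = NULL) {
  series <- as_tibble(as.data.frame(series))
  if (!all(c("start_s", "end_s") %in% names(series))) {
    abort("`series` needs columns `start_s` and `end_s`.",
          class = "ccrate_annotation_error")
  }
  series <- dplyr::arrange(series[, c("start_s", "end_s")], .data$start_s)
  if (nrow(series) > 0) {
    if (any(series$end_s <= series$start_s)) {
      abort("Every series must have end_s > start_s.",
            class = "ccrate_annotation_error")
    }
    if (nrow(series) > 1 &&
        any(series$start_s[-1] < series$end_s[-nrow(series)])) {
      abort("Series intervals overlap.", class = "ccrate_annotation_error")
    }
  }
  instances_s <- sort(as.numeric(instances_s))
  if (length(instances_s)) {
    inside <- vapply(instances_s, function(t) {
      any(t >= series$start_s & t <= series$end_s)
    }, logical(1))
    if (!all(inside)) {
      abort(sprintf("Compression instant at %.3f s lies outside every series.",
                    instances_s[which(!inside)[1]]),
            class = "ccrate_annotation_error")
    }
    if (length(instances_s) > 1) {
      gaps <- diff(instances_s)
      same <- vapply(seq_len(length(instances_s) - 1), function(i) {
        any(instances_s[i] >= series$start_s & instances_s[i + 1] <= series$end_s)
      }, logical(1))
      if (any(same & gaps <= 0.2)) {
        abort("Consecutive compression instants within a series must be > 0.2 s apart.",
              class = "ccrate_annotation_error")
      }
    }
  }
  if (is.null(excluded)) {
    excluded <- tibble(start_s = numeric(), end_s = numeric())
  } else {
    excluded <- as_tibble(as.data.frame(excluded))[, c("start_s", "end_s")]
  }
  structure(
    list(series = series, instances_s = instances_s, excluded = excluded),
    class = "cc_annotation"
  )
}

#' @export
print.cc_annotation <- function(x, ...) {
  cat(sprintf("<cc_annotation> %d series, %d compression instants",
              nrow(x$series), length(x$instances_s)))
  if (nrow(x$excluded)) cat(sprintf(", %d excluded intervals", nrow(x$excluded)))
  cat("\n")
  if (nrow(x$series)) {
    tot <- sum(x$series$end_s - x$series$start_s)
    cat(sprintf("  compression time: %.1f s\n", tot))
  }
  invisible(x)
}

#' Read or write episode annotations as JSON
#'
#' The schema is
#' `{"series": [{"start_s": ..., "end_s": ...}], "instances_s": [...],`
#' `"excluded": [{"start_s": ..., "end_s": ...}]}` with `excluded` optional.
#' All invariants of [episode_annotation()] are enforced on read.
#'
#' @param path Path to a JSON file.
#' @return `read_annotation_json()` returns a `cc_annotation`;
#'   `write_annotation_json()` returns `path` invisibly.
#' @export
read_annotation_json <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Annotation file not found: %s", path),
          class = "ccrate_io_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  series <- if (is.null(raw$series) || length(raw$series) == 0) {
    tibble(start_s = numeric(), end_s = numeric())
  } else {
    as_tibble(raw$series)
  }
  excluded <- if (is.null(raw$excluded) || length(raw$excluded) == 0) {
    NULL
  } else {
    as_tibble(raw$excluded)
  }
  episode_annotation(series, instances_s = raw$instances_s %||% numeric(),
                     excluded = excluded)
}

#' @param annotation A `cc_annotation` object.
#' @rdname read_annotation_json
#' @export
write_annotation_json <- function(annotation, path) {
  stopifnot(inherits(annotation, "cc_annotation"))
  payload <- list(
    series = annotation$series,
    instances_s = annotation$instances_s
  )
  if (nrow(annotation$excluded)) payload$excluded <- annotation$excluded
  jsonlite::write_json(payload, path, digits = NA, dataframe = "rows")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
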