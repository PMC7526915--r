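#' Plot an impedance signal
#'
#' @param object A [impedance_signal()].
#' @param annotation Optional [episode_annotation()]; annotated compression
#'   series are shaded and instants marked.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ti_signal <- function(object, annotation = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                            y = .data$impedance_ohm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "impedance (ohm)") +
    ggplot2::theme_minimal()
  if (!is.null(annotation) && nrow(annotation$series)) {
    p <- p +
      ggplot2::geom_rect(
        data = annotation$series,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                     ymin = -Inf, ymax = Inf),
        inherit.aes = FALSE, fill = "steelblue", alpha = 0.15
      )
  }
  p
}

#' Plot a detection track
#'
#' Shows the per-window rate estimates over time: detected windows as points
#' at their estimated rate, pauses at zero. If window references are
#' supplied, the reference rate is overlaid.
#'
#' @param results Output of [detect_compressions()].
#' @param references Optional output of [label_windows()].
#' @return A ggplot object.
#' @export
plot_detections <- function(results, references = NULL) {
  df <- dplyr::mutate(results, mid_s = (.data$start_s + .data$end_s) / 2)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_s, y = .data$rate_cpm)) +
    ggplot2::geom_step(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$detected), size = 1.2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40")) +
    ggplot2::labs(x = "time (s)", y = "compression rate (cpm)",
                  colour = "detected") +
    ggplot2::theme_minimal()
  if (!is.null(references)) {
    ref <- dplyr::inner_join(df, references, by = "window_index")
    ref <- ref[!is.na(ref$reference_rate_cpm), ]
    if (nrow(ref)) {
      p <- p + ggplot2::geom_point(
        data = ref,
        ggplot2::aes(y = .data$reference_rate_cpm),
        shape = 3, colour = "black", size = 1
      )
    }
  }
  p
}

#' Plot an evaluation report
#'
#' Per-episode distributions of the four figures of merit as box plots, the
#' usual way per-episode detector performance is displayed.
#'
#' @param object A `cc_evaluation` from [evaluate_corpus()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cc_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_episode[, c("episode", "Se", "PPV", "Sp", "NPV")],
    cols = c("Se", "PPV", "Sp", "NPV"),
    names_to = "metric", values_to = "value"
  )
  long$metric <- factor(long$metric, levels = c("Se", "PPV", "Sp", "NPV"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4, outlier.size = 0.8) +
    ggplot2::labs(x = NULL, y = "percent (per episode)") +
    ggplot2::theme_minimal()
}
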