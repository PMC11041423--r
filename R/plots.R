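#' Bland-Altman plot
#'
#' Scatter of pairwise differences against pairwise means with the bias
#' (solid) and limits of agreement (dashed) drawn as horizontal lines.
#'
#' @param object A [bland_altman()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  df <- tidy(object)
  ylab <- if (object$mode == "percent") "difference (%)" else "difference"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(x = "pairwise mean", y = ylab,
                  title = sprintf("Bland-Altman: bias %.3g, LoA [%.3g, %.3g]",
                                  object$bias, object$loa_lower,
                                  object$loa_upper)) +
    ggplot2::theme_minimal()
}

#' Plot a recording with its segmentation
#'
#' Draws the (smoothed) waveform over a time window with detected cycle
#' boundaries as vertical lines; deep cycles are highlighted.
#'
#' @param signal A [breath_signal()].
#' @param seg Optional `breath_segmentation` from the same signal.
#' @param window Optional `c(from_s, to_s)` time window.
#' @return A ggplot object.
#' @export
plot_signal <- function(signal, seg = NULL, window = NULL) {
  assert_signal(signal)
  df <- tibble::as_tibble(signal)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time_s >= window[[1]],
                        .data$time_s <= window[[2]])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = signal_units(signal)) +
    ggplot2::theme_minimal()
  if (!is.null(seg) && nrow(seg) > 0) {
    b <- tibble::as_tibble(seg)
    if (!is.null(window)) {
      b <- dplyr::filter(b, .data$start_s >= window[[1]],
                         .data$start_s <= window[[2]])
    }
    p <- p +
      ggplot2::geom_vline(data = b,
                          ggplot2::aes(xintercept = .data$start_s,
                                       colour = .data$label),
                          linetype = "dotted", alpha = 0.7) +
      ggplot2::scale_colour_manual(values = c(normal = "grey40",
                                              deep = "firebrick"))
  }
  p
}

#' Device-comparison box plot
#'
#' Side-by-side box plots of a parameter measured by both devices, the
#' median/IQR comparison used to eyeball device equivalence.
#'
#' @param pairs A tibble with columns `rhs` and `pnt` (one row per paired
#'   measurement), e.g. `report$dba_pairs` from [run_experiment()].
#' @param parameter Axis label for the parameter.
#' @return A ggplot object.
#' @export
plot_box_comparison <- function(pairs, parameter = "value") {
  stopifnot(all(c("rhs", "pnt") %in% names(pairs)))
  long <- tidyr::pivot_longer(pairs, c("rhs", "pnt"),
                              names_to = "device", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$device, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = parameter) +
    ggplot2::theme_minimal()
}
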