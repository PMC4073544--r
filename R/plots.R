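#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the two-limb PD ROC
#'
#' Draws the polygonal ROC path `P0..P6` with the operating points
#' highlighted, optionally overlaying the smooth curve of a fitted
#' signal-detection baseline.
#'
#' @param object A `pd_roc` tibble from [operating_points()].
#' @param sdt Optional `pd_sdt` fit to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(operating_points(theta_pd(0.55, 0.5, 0.73, 0.4, 0.25)))
#' @export
autoplot.pd_roc <- function(object, sdt = NULL, ...) {
  operating <- object[object$point %in% c("P2", "P3", "P4"), ]
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(
      intercept = 0, slope = 1,
      linetype = "dotted", colour = "grey50"
    ) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::geom_point(data = operating, shape = 22, size = 3, fill = "white") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$point),
      nudge_x = 0.035, nudge_y = -0.025, size = 3
    ) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "False-alarm rate", y = "Hit rate",
      title = "PD model ROC"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(sdt)) {
    p <- p + ggplot2::geom_line(
      data = sdt_roc_curve(sdt),
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "steelblue", linetype = "dashed"
    )
  }
  p
}

#' Plot posterior distributions of the PD parameters
#'
#' @param object A `pd_posterior` fit.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object, one facet per parameter.
#' @export
autoplot.pd_posterior <- function(object, bins = 50, ...) {
  draws <- tibble::as_tibble(as.data.frame(object$draws))
  long <- tidyr::pivot_longer(draws, dplyr::everything(),
    names_to = "parameter", values_to = "value"
  )
  long$parameter <- factor(long$parameter, levels = .theta_names)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(
      bins = bins, boundary = 0,
      fill = "grey70", colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(
      x = "Parameter value", y = "Draws",
      title = sprintf("PD posterior (%s)", toupper(object$method))
    ) +
    ggplot2::theme_minimal()
}
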