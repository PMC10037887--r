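#' Plot a recovery grid as a heatmap
#'
#' @param object A `recovery_grid` from [run_grid()].
#' @param metric Cell column to fill by (default `"mean_accuracy"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_grid
#' @export
autoplot.recovery_grid <- function(object, metric = "mean_accuracy", ...) {
  ggplot2::ggplot(
    object$cells,
    ggplot2::aes(factor(.data$p), factor(.data$depth), fill = .data[[metric]])
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f", .data[[metric]])), size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "#2166ac", high = "#b2182b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "error rate p", y = "sequencing depth", fill = metric) +
    ggplot2::theme_minimal()
}

#' Plot a depth curve with its thresholds
#'
#' @param object A `depth_curve` from [min_depth()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot depth_curve
#' @export
autoplot.depth_curve <- function(object, ...) {
  col <- object$metric_column
  ggplot2::ggplot(object$cells,
                  ggplot2::aes(.data$depth, .data[[col]])) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = object$thresholds,
      ggplot2::aes(yintercept = .data$threshold), linetype = "dashed",
      colour = "grey50"
    ) +
    ggplot2::geom_vline(
      data = dplyr::filter(object$thresholds, !is.na(.data$min_depth)),
      ggplot2::aes(xintercept = .data$min_depth), linetype = "dotted",
      colour = "firebrick"
    ) +
    ggplot2::labs(x = "sequencing depth", y = col,
                  title = sprintf("p = %g", object$p)) +
    ggplot2::theme_minimal()
}

#' Plot a phase scan: depth improvement against error rate
#'
#' @param object A `phase_scan` from [phase_scan()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_scan
#' @export
autoplot.phase_scan <- function(object, ...) {
  ggplot2::ggplot(object$indicator,
                  ggplot2::aes(.data$p, .data$improvement)) +
    ggplot2::geom_hline(yintercept = object$margin, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$depth_helps)) +
    ggplot2::labs(x = "error rate p",
                  y = "metric improvement (deep - shallow)",
                  colour = "depth helps") +
    ggplot2::theme_minimal()
}
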