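# ggplot2 views of the analysis results.

#' MI-vs-r scatter with the MPMI contour
#'
#' @param records A `btp_pairs` table.
#' @param model Contour model to overlay (default: the records' config, or
#'   the calibrated default).
#' @param colour_by Column mapped to colour ("linearity",
#'   "transition_class" or "pair_type").
#' @return A ggplot.
#' @export
plot_mi_r <- function(records, model = NULL, colour_by = "linearity") {
  if (is.null(model)) {
    cfg <- attr(records, "config")
    model <- if (!is.null(cfg)) cfg$contour else contour_default()
  }
  curve <- tibble(r = seq(-0.995, 0.995, by = 0.005))
  curve$mi <- mpmi_contour(curve$r, model)
  ggplot2::ggplot(records, ggplot2::aes(x = .data$r, y = .data$mi)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curve, linetype = "dashed", colour = "darkgreen") +
    ggplot2::coord_cartesian(ylim = c(0, max(records$mi) * 1.05)) +
    ggplot2::labs(x = "circular correlation r", y = "MI (nats)",
                  colour = colour_by) +
    ggplot2::theme_minimal()
}

#' @rdname plot_mi_r
#' @param object A `btp_pairs` table.
#' @param ... Passed to [plot_mi_r()].
#' @export
autoplot.btp_pairs <- function(object, ...) plot_mi_r(object, ...)

#' Heatmap of a joint angle distribution or difference grid
#'
#' @param object A `btp_dist2d` (or pass a matrix to `plot_joint_grid()`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.btp_dist2d <- function(object, ...) plot_joint_grid(object$p, object$n_bins)

#' @rdname autoplot.btp_dist2d
#' @param grid Probability or difference matrix (rows = x-bin).
#' @param n_bins Bins per axis.
#' @export
plot_joint_grid <- function(grid, n_bins = nrow(grid)) {
  w <- 360 / n_bins
  df <- tibble(
    x = rep(-180 + w * (seq_len(n_bins) - 0.5), times = n_bins),
    y = rep(-180 + w * (seq_len(n_bins) - 0.5), each = n_bins),
    p = as.vector(grid)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (degrees)", y = "y (degrees)", fill = "p") +
    ggplot2::theme_minimal()
}

#' Subset-analysis overlay plot
#'
#' Subset MI-vs-r points with the full-trajectory value highlighted;
#' point colour gives the subset's joint-peak count.
#'
#' @param object A `btp_subsets` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.btp_subsets <- function(object, ...) {
  ref <- attr(object, "reference")
  curve <- tibble(r = seq(-0.995, 0.995, by = 0.005))
  curve$mi <- mpmi_contour(curve$r)
  ggplot2::ggplot(object, ggplot2::aes(.data$r, .data$mi)) +
    ggplot2::geom_line(data = curve, linetype = "dashed", colour = "darkgreen") +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$n_joint_peaks)), size = 2) +
    ggplot2::geom_point(data = ref, shape = 8, size = 4, colour = "black") +
    ggplot2::coord_cartesian(ylim = c(0, max(object$mi, ref$mi) * 1.1)) +
    ggplot2::labs(x = "circular correlation r", y = "MI (nats)",
                  colour = "joint peaks") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
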