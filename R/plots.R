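# Figure-style plots: per-group scatter of a polarity metric with
# mean +/- SD error bars, and division-angle dot plots.

#' Scatter a polarity metric by group with mean and SD
#'
#' The standard presentation for per-cell polarity statistics: one jittered
#' point per cell, a crossbar at the group mean and error bars spanning
#' mean plus/minus one standard deviation.
#'
#' @param data Data frame with one row per cell.
#' @param metric Column name (string) of the metric, e.g. `"P"`, `"S"` or
#'   `"ratio"`.
#' @param group Column name (string) of the grouping variable.
#' @return A ggplot object.
#' @examples
#' df <- data.frame(P = runif(20), genotype = rep(c("a", "b"), 10))
#' plot_polarity(df, "P", "genotype")
#' @export
plot_polarity <- function(data, metric = "P", group = "group") {
  stopifnot(all(c(metric, group) %in% names(data)))
  ggplot2::ggplot(data,
    ggplot2::aes(.data[[group]], .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, colour = "#2166ac") +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.35,
      linewidth = 0.4) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_sdl,
      fun.args = list(mult = 1), geom = "errorbar", width = 0.2) +
    ggplot2::theme_minimal()
}

#' Dot plot of signed division angles by group
#'
#' Shows each division's signed angle relative to the anterior-posterior
#' axis (0 degrees), with the axis conventions of the package: positive
#' angles are clockwise in the viewer's frame.
#'
#' @param data Data frame with one row per division.
#' @param angle Column name (string) of the signed angle in degrees.
#' @param group Column name (string) of the grouping variable.
#' @return A ggplot object.
#' @export
plot_division_angles <- function(data, angle = "angle_deg", group = "group") {
  stopifnot(all(c(angle, group) %in% names(data)))
  ggplot2::ggplot(data,
    ggplot2::aes(.data[[group]], .data[[angle]])) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.6, colour = "#b2182b") +
    ggplot2::scale_y_continuous(limits = c(-180, 180),
      breaks = seq(-180, 180, 90)) +
    ggplot2::labs(y = "division angle (deg, A-P axis = 0)") +
    ggplot2::theme_minimal()
}

#' Render a synthetic cell image as a ggplot raster
#'
#' @param object,... A `crescent_image` from [simulate_cell_image()];
#'   further arguments are ignored.
#' @return A ggplot object.
#' @export
autoplot.crescent_image <- function(object, ...) {
  img <- object$image
  df <- tidyr::expand_grid(y = 0:(nrow(img) - 1), x = 0:(ncol(img) - 1))
  df$value <- as.vector(t(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "grey value") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}
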