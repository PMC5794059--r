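# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.colony_trajectory <- function(object, species = "A", ...) {
  df <- dplyr::filter(as_tibble(object), .data$species == !!species)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = factor(.data$cell))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = paste0(species, " (a.u.)"),
                  colour = "cell") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ase_series <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$ase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "ASE (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(fit) && !fit$perfect_synchrony) {
    env <- tibble::tibble(time = object$time,
                          ase = fit$a * exp(-fit$r * object$time))
    p <- p + ggplot2::geom_line(data = env, linetype = "dashed",
                                colour = "red")
  }
  p
}

#' @export
autoplot.bifurcation_map <- function(object, fill = c("label", "period",
                                                      "amplitude"), ...) {
  fill <- match.arg(fill)
  ax <- attr(object, "axis_x")
  ay <- attr(object, "axis_y")
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data[[fill]])) +
    ggplot2::labs(x = ax$name, y = ay$name) +
    ggplot2::theme_minimal()
}

#' Difference heatmap of a robustness grid
#'
#' @param grid A `robustness_grid`.
#' @param metric `"iase"` (plots IASE_danino - IASE_hotfm) or `"r"`
#'   (plots r_danino - r_hotfm).
#' @param thresholded Show only the sign of the difference.
#' @return A ggplot object.
#' @export
plot_robustness_map <- function(grid, metric = c("iase", "r"),
                                thresholded = FALSE) {
  metric <- match.arg(metric)
  df <- dplyr::filter(grid, .data$common, !is.na(.data$iase_danino))
  df$diff <- if (metric == "iase") df$iase_danino - df$iase_hotfm
             else df$r_danino - df$r_hotfm
  if (thresholded) df$diff <- factor(sign(df$diff))
  ax <- attr(grid, "axis_x")
  ay <- attr(grid, "axis_y")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = ax$name, y = ay$name,
                  fill = paste0(metric, " difference")) +
    ggplot2::theme_minimal()
}
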