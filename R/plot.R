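#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_point geom_path
#'   scale_fill_viridis_c coord_equal coord_polar labs theme_minimal
#'   geom_rect annotate
NULL

#' Plot a firing-rate map
#'
#' @param object A `rate_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x_cm, y = .data$y_cm, fill = .data$rate_hz)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90", name = "Hz") +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
}

#' Plot a circular tuning curve in polar coordinates
#'
#' @param object A `circ_tuning` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.circ_tuning <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot(df, aes(x = .data$bin_center_deg, y = .data$rate_hz)) +
    geom_line() +
    coord_polar(start = -pi / 2, direction = -1) +
    labs(x = NULL, y = "rate (Hz)",
         subtitle = sprintf("MVL %.3f, preferred %.0f deg",
                            attr(object, "mvl"), attr(object, "preferred_deg"))) +
    theme_minimal()
}

#' Plot an egocentric MVL map with its MVL_max location
#'
#' @param object An `mvl_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mvl_map <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$x_cm, y = .data$y_cm, fill = .data$mvl)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90", name = "MVL") +
    annotate("point", x = object$mvl_max_loc[1], y = object$mvl_max_loc[2],
             colour = "red", shape = 4, size = 3) +
    coord_equal() +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
}

#' Plot a session trajectory with the goal zone
#'
#' @param tracking Tracking tibble.
#' @param arena An [arena_geometry()].
#' @return A ggplot.
#' @export
plot_trajectory <- function(tracking, arena) {
  gz <- goal_zone(arena)
  ggplot(tracking, aes(x = .data$x_cm, y = .data$y_cm)) +
    geom_path(alpha = 0.4, linewidth = 0.2) +
    geom_rect(xmin = gz$x0, xmax = gz$x0 + gz$side,
              ymin = gz$y0, ymax = gz$y0 + gz$side,
              fill = NA, colour = "red") +
    coord_equal(xlim = c(0, arena$side_length), ylim = c(0, arena$side_length)) +
    labs(x = "x (cm)", y = "y (cm)") +
    theme_minimal()
}
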