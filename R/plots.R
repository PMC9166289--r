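#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a gridded map
#'
#' @param object An `rl_map` (state-value, diverse-density, occupancy or
#'   tuning map).
#' @param ... Unused.
#' @return A ggplot raster of the map; unvisited bins are blank.
#' @export
autoplot.rl_map <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = object$kind, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Quiver plot of a policy map
#'
#' Unit vectors show each bin's preferred movement direction; color shows
#' the resultant magnitude.
#'
#' @param object An `rl_policy_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rl_policy_map <- function(object, ...) {
  d <- tidy(object)
  d$ux <- object$ux; d$uy <- object$uy
  d <- d[is.finite(d$value) & d$value > 0, ]
  sx <- object$spec$extent[1] / object$spec$nx * 0.45
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + .data$ux * sx,
                                       yend = .data$y + .data$uy * sx,
                                       color = .data$value),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "mm"))) +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(color = "resultant", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot trajectories colored by time
#'
#' @param traj A trajectory tibble.
#' @param trials Trial ids to draw (default: first 8).
#' @return A ggplot of the object paths.
#' @export
plot_trajectories <- function(traj, trials = NULL) {
  if (is.null(trials)) trials <- utils::head(unique(traj$trial), 8)
  d <- traj[traj$trial %in% trials, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  color = .data$t, group = .data$trial)) +
    ggplot2::geom_path() +
    ggplot2::scale_color_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~trial) +
    ggplot2::labs(color = "time", x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Training-curve plot
#'
#' @param log A training log tibble from [train_agent()].
#' @return A ggplot of mean episode return against environment steps.
#' @export
plot_training <- function(log) {
  ggplot2::ggplot(log[is.finite(log$mean_return), ],
                  ggplot2::aes(x = .data$steps, y = .data$mean_return)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "environment steps", y = "mean discounted return") +
    ggplot2::theme_minimal()
}

#' @export
tidy.rl_classification <- function(x, ...) as_tibble(x)

#' @export
glance.rl_classification <- function(x, ...) {
  tibble(n_units = nrow(x),
         n_classified = sum(x$classified, na.rm = TRUE),
         frac_classified = mean(x$classified, na.rm = TRUE),
         n_excluded = sum(!is.na(x$excluded)))
}
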