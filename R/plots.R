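#' Plot tabulated interaction factors
#'
#' One panel per factor, point size proportional to the per-bin record
#' count, so thinly populated (noise-dominated) bins are visually
#' de-emphasized exactly as they are down-weighted in the fits.
#'
#' @param object A `bc_factorization` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bc_factorization <- function(object, ...) {
  d <- tidy.bc_factorization(object)
  ggplot2::ggplot(d, ggplot2::aes(x = bin_center, y = value,
                                  size = weight)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7, show.legend = FALSE) +
    ggplot2::facet_wrap(~fn, scales = "free") +
    ggplot2::scale_size_area(max_size = 2) +
    ggplot2::labs(x = NULL, y = "factor value",
                  title = sprintf("%s-response factorization", object$mode))
}

#' Plot a trajectory inside the arena
#'
#' @param traj Trajectory with `time_s`, `fish_id`, `x_mm`, `y_mm`.
#' @param radius_mm Arena radius (mm); defaults to the trajectory
#'   attribute.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(traj, radius_mm = attr(traj, "radius_mm")) {
  need_cols(traj, c("time_s", "fish_id", "x_mm", "y_mm"))
  check_radius(radius_mm)
  th <- seq(-pi, pi, length.out = 361)
  wall <- tibble::tibble(x_mm = radius_mm * cos(th),
                         y_mm = radius_mm * sin(th))
  ggplot2::ggplot(traj, ggplot2::aes(x_mm, y_mm)) +
    ggplot2::geom_path(data = wall, colour = "grey40") +
    ggplot2::geom_path(ggplot2::aes(colour = factor(fish_id)),
                       show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' Plot the per-kick summary distributions
#'
#' @param stats Output of [kick_statistics()].
#' @return A ggplot object, one panel per variable.
#' @export
plot_kick_statistics <- function(stats) {
  ggplot2::ggplot(stats$pdf, ggplot2::aes(bin_center, density)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = NULL, y = "density")
}
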