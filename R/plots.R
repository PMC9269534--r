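# ggplot2 views of the main result types.

#' Plot a joint-angle series
#'
#' One line per movement channel over time, with off-axis residual shown as
#' a light band when present.
#'
#' @param object A `"joint_angles"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.joint_angles <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, intersect(c("t", "flexion_extension", "pronation_supination"),
                       names(object))],
    -"t", names_to = "channel", values_to = "angle"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$angle,
                                     colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "angle [deg]", colour = NULL,
                  title = "Elbow joint angles") +
    ggplot2::theme_minimal()
}

#' Plot a nine-channel sensor stream
#'
#' Facets the accelerometer, gyroscope and magnetometer triads.
#'
#' @param object An `"imu_stream"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.imu_stream <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "ax", "ay", "az", "gx", "gy", "gz",
                                  "mx", "my", "mz")],
    -"t", names_to = "channel", values_to = "value"
  )
  long$triad <- dplyr::recode(substr(long$channel, 1, 1),
                              a = "accelerometer [m/s^2]",
                              g = "gyroscope [deg/s]",
                              m = "magnetometer [uT]")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value,
                                     colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~triad, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a two-system comparison
#'
#' Bar chart of RMSE and absolute bias per movement channel.
#'
#' @param object A `"rom_comparison"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rom_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("channel", "rmse", "bias")],
    -"channel", names_to = "metric", values_to = "degrees"
  )
  long$degrees <- abs(long$degrees)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$channel, y = .data$degrees,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "degrees",
                  title = "Two-system agreement") +
    ggplot2::theme_minimal()
}

#' Plot an aligned series pair
#'
#' Overlays the two aligned series and annotates the estimated lag.
#'
#' @param object An `"aligned_pair"` from [align_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aligned_pair <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"t",
                              names_to = "series", values_to = "angle")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$angle,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time [s]", y = "angle [deg]", colour = NULL,
      subtitle = sprintf("estimated lag: %.3f s", attr(object, "lag"))
    ) +
    ggplot2::theme_minimal()
}
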