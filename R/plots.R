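#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an IMU recording
#'
#' Faceted line plot of the six signal channels against time, optionally
#' with shaded stride intervals.
#'
#' @param object an `imu_recording`.
#' @param strides optional stride list to shade.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.imu_recording <- function(object, strides = NULL, ...) {
  rate <- sampling_rate(object)
  cols <- imu_cols(imu_frame(object))
  d <- tibble::as_tibble(object)[, cols]
  d$time <- (seq_len(nrow(d)) - 1) / rate
  long <- tidyr::pivot_longer(d, -"time", names_to = "channel")
  long$sensor <- ifelse(startsWith(long$channel, "acc"),
                        "acceleration [m/s²]",
                        "angular velocity [deg/s]")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                          colour = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~sensor, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(strides) && nrow(strides) > 0) {
    sh <- tibble::tibble(xmin = strides$start / rate,
                         xmax = strides$end / rate)
    p <- p + ggplot2::geom_rect(
      data = sh, ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                              ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.1, fill = "grey40")
  }
  p
}

#' Plot a reconstructed trajectory
#'
#' Sagittal-plane view (forward displacement vs height) of a foot
#' trajectory.
#'
#' @param object a `trajectory`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.trajectory <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$pos_x, .data$pos_z)) +
    ggplot2::geom_path(colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "forward displacement [m]", y = "height [m]") +
    ggplot2::theme_minimal()
}

#' Plot segmentation / event-detection results
#'
#' `plot_segmentation()` shows the body-frame `gyr_ml` trace with shaded
#' detected strides and, if given, event markers.
#'
#' @param rec a body-frame `imu_recording`.
#' @param strides a stride list.
#' @param events optional event list from [detect_events()].
#' @return a ggplot.
#' @export
plot_segmentation <- function(rec, strides, events = NULL) {
  rate <- sampling_rate(rec)
  d <- tibble::tibble(time = (seq_len(nrow(rec)) - 1) / rate,
                      gyr_ml = rec$gyr_ml)
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$gyr_ml)) +
    ggplot2::geom_rect(
      data = tibble::tibble(xmin = strides$start / rate,
                            xmax = strides$end / rate),
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "seagreen") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time [s]", y = "gyr_ml [deg/s]") +
    ggplot2::theme_minimal()
  if (!is.null(events)) {
    ev <- tidyr::pivot_longer(
      events[events$detectable, c("tc", "ic", "min_vel")],
      dplyr::everything(), names_to = "event", values_to = "sample")
    ev$time <- ev$sample / rate
    p <- p + ggplot2::geom_vline(
      data = ev, ggplot2::aes(xintercept = .data$time,
                              colour = .data$event),
      linetype = "dashed", alpha = 0.7)
  }
  p
}

#' @rdname stridewise-tidiers
#' @param object a `gait_analysis`.
#' @export
autoplot.gait_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(object$parameters, -"stride_id",
                              names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(.data$stride_id, .data$value)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "stride", y = NULL) +
    ggplot2::theme_minimal()
}
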