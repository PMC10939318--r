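#' Detect zero-velocity (ZUPT) regions
#'
#' Window-based thresholding detectors for foot stillness, used both as
#' pseudo-measurements for the error-state Kalman filter and as anchors
#' for dedrifted integration. Overlapping windows (default 50% overlap)
#' are evaluated, windows whose statistic falls strictly below `threshold`
#' are marked static, and passing windows are merged into maximal regions.
#' A final window aligned with the end of the recording is always
#' evaluated, so every sample is covered by at least one window.
#'
#' Detector statistics (per window):
#' * `ared` (angular-rate energy): mean of the squared gyroscope norm,
#'   in (deg/s)^2;
#' * `norm`: a metric (`mean`, `max` or `variance`) of the chosen sensor's
#'   sample norm (deg/s for `gyr`, m/s^2 for `acc`);
#' * `shoe` (SHOE/GLRT): mean of
#'   `||acc_k - g * a_bar/||a_bar|| ||^2 / sigma_a^2 + ||gyr_k||^2 /
#'   sigma_g^2`, where `a_bar` is the window-mean acceleration, i.e. the
#'   gravity direction is estimated per window. In the limit
#'   `sigma_a -> Inf` SHOE degenerates to ARED scaled by `1/sigma_g^2`.
#'
#' Default thresholds are calibrated on the synthetic simulator so that a
#' still foot with ~1 deg/s gyroscope noise passes; they are not normative.
#'
#' @param rec an `imu_recording`.
#' @param detector one of `"ared"`, `"norm"`, `"shoe"`.
#' @param window_length window length in seconds.
#' @param window_overlap fractional window overlap in `[0, 1)`.
#' @param threshold detector-specific threshold (see statistics above).
#' @param sensor,metric for `"norm"`: which sensor and which metric.
#' @param sigma_a,sigma_g for `"shoe"`: accelerometer (m/s^2) and gyroscope
#'   (deg/s) noise scales.
#' @param gravity gravity magnitude in m/s^2.
#' @return an interval list of maximal static regions.
#' @export
detect_zupt <- function(rec, detector = c("ared", "norm", "shoe"),
                        window_length = 0.1, window_overlap = 0.5,
                        threshold = NULL,
                        sensor = c("gyr", "acc"),
                        metric = c("mean", "max", "variance"),
                        sigma_a = 0.5, sigma_g = 1,
                        gravity = 9.81) {
  detector <- match.arg(detector)
  sensor <- match.arg(sensor)
  metric <- match.arg(metric)
  stopifnot(window_length > 0, window_overlap >= 0, window_overlap < 1,
            sigma_a > 0, sigma_g > 0)
  if (is.null(threshold)) {
    threshold <- switch(detector, ared = 25, norm = 34, shoe = 50)
  }
  rate <- sampling_rate(rec)
  n <- nrow(rec)
  w <- max(1L, as.integer(round(window_length * rate)))
  if (w > n) stop("ZUPT window (", w, " samples) is longer than the recording")
  hop <- max(1L, as.integer(round(w * (1 - window_overlap))))
  starts <- seq.int(0L, n - w, by = hop)
  if (starts[length(starts)] != n - w) starts <- c(starts, n - w)

  acc <- acc_matrix(rec)
  gyr <- gyr_matrix(rec)
  stat <- vapply(starts, function(s) {
    idx <- (s + 1):(s + w)
    switch(detector,
      ared = mean(rowSums(gyr[idx, , drop = FALSE]^2)),
      norm = {
        x <- if (sensor == "gyr") gyr[idx, , drop = FALSE] else acc[idx, , drop = FALSE]
        nx <- sqrt(rowSums(x^2))
        switch(metric, mean = mean(nx), max = max(nx),
               variance = stats::var(nx) * (length(nx) - 1) / length(nx))
      },
      shoe = {
        a <- acc[idx, , drop = FALSE]
        abar <- colMeans(a)
        gdir <- abar / sqrt(sum(abar^2))
        resid <- a - matrix(gravity * gdir, nrow = length(idx), ncol = 3,
                            byrow = TRUE)
        mean(rowSums(resid^2) / sigma_a^2 +
               rowSums(gyr[idx, , drop = FALSE]^2) / sigma_g^2)
      }
    )
  }, 0)
  pass <- starts[stat < threshold]
  if (length(pass) == 0) return(interval_list())
  merge_intervals(pass, pass + w)
}
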