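#' Full single-sensor gait analysis pipeline
#'
#' Chains the package's stages on one foot-worn sensor-frame recording:
#'
#' 1. gravity alignment ([align_to_gravity()]),
#' 2. body-frame conversion ([to_body_frame()]),
#' 3. stride segmentation by subsequence DTW on `gyr_ml`
#'    ([subsequence_dtw()]),
#' 4. gait-event detection ([detect_events()]) and re-segmentation to
#'    min_vel strides ([to_min_vel_strides()]),
#' 5. ZUPT detection ([detect_zupt()]) and trajectory reconstruction with
#'    the ZUPT-aided error-state Kalman filter + RTS smoothing
#'    ([rts_kalman()]),
#' 6. temporal and spatial parameters ([temporal_parameters()],
#'    [spatial_parameters()]).
#'
#' @param rec a sensor-frame `imu_recording`.
#' @param side `"left"` or `"right"`.
#' @param template stride template for segmentation; defaults to the
#'   packaged synthetic template (valid for 204.8 Hz signals).
#' @param max_cost DTW acceptance threshold.
#' @param zupt_detector,zupt_threshold ZUPT detector choice and threshold.
#' @param lowpass_cutoff `ic` low-pass cutoff in Hz, or `NULL` for the
#'   unfiltered event detector.
#' @param ... further arguments passed to [rts_kalman()].
#' @return an object of class `gait_analysis`: list with `strides`,
#'   `events`, `min_vel_strides`, `min_vel_events`, `zupts`, `kalman`
#'   (full [rts_kalman()] result), `parameters` (per-stride tibble) and
#'   `sampling_rate`.
#' @examples
#' bundle <- simulate_session(gait_profile(n_strides = 5))
#' ga <- gait_pipeline(bundle$recording, side = "left")
#' dplyr::glimpse(ga$parameters)
#' @export
gait_pipeline <- function(rec, side, template = NULL, max_cost = 5,
                          zupt_detector = "ared", zupt_threshold = NULL,
                          lowpass_cutoff = NULL, ...) {
  if (is.null(template)) template <- default_stride_template()
  rate <- sampling_rate(rec)
  if (abs(rate - template$sampling_rate) > 1e-9) {
    stop("recording rate (", rate, " Hz) differs from template rate (",
         template$sampling_rate, " Hz); resample first")
  }
  aligned <- align_to_gravity(rec)$recording
  body <- to_body_frame(aligned, side)
  strides <- subsequence_dtw(body$gyr_ml, template, max_cost = max_cost)
  events <- detect_events(body, strides, lowpass_cutoff = lowpass_cutoff)
  mv <- to_min_vel_strides(events)
  zupts <- detect_zupt(aligned, zupt_detector, threshold = zupt_threshold)
  kal <- rts_kalman(aligned, zupts, ...)
  temporal <- temporal_parameters(mv$events, rate)
  params <- spatial_parameters(kal$trajectory, mv$strides, temporal)
  structure(list(
    strides = strides, events = events,
    min_vel_strides = mv$strides, min_vel_events = mv$events,
    zupts = zupts, kalman = kal, parameters = params,
    sampling_rate = rate
  ), class = "gait_analysis")
}

#' @export
print.gait_analysis <- function(x, ...) {
  cat(sprintf(
    "# gait analysis: %d segmented strides, %d min_vel strides, %d ZUPT regions\n",
    nrow(x$strides), nrow(x$min_vel_strides), nrow(x$zupts)))
  print(glance(x))
  invisible(x)
}
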