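#' Temporal gait parameters from event lists
#'
#' Computes per-stride temporal parameters from consecutive detected
#' events:
#' `stride_time_k = (ic_k - ic_{k-1}) / rate`,
#' `swing_time_k = (ic_k - tc_k) / rate`,
#' `stance_time_k = stride_time_k - swing_time_k`.
#' The first stride of each unbroken sequence has no preceding initial
#' contact, so only its swing time is defined; missing events yield `NA`
#' parameters (flagged, never zero).
#'
#' @param events an event list tibble (see [detect_events()]).
#' @param rate sampling rate in Hz.
#' @return a tibble with `stride_id`, `stride_time`, `swing_time`,
#'   `stance_time` in seconds.
#' @export
temporal_parameters <- function(events, rate) {
  stopifnot(rate > 0)
  ok <- events$detectable & !is.na(events$ic) & !is.na(events$tc)
  ic_prev <- rep(NA_integer_, nrow(events))
  # previous ic within an unbroken run of detectable strides
  run <- cumsum(!ok)
  for (r in split(seq_len(nrow(events)), run)) {
    r <- r[ok[r]]
    if (length(r) > 1) ic_prev[r[-1]] <- events$ic[r[-length(r)]]
  }
  stride_time <- (events$ic - ic_prev) / rate
  swing_time <- ifelse(ok, (events$ic - events$tc) / rate, NA_real_)
  tibble::tibble(
    stride_id = events$stride_id,
    stride_time = stride_time,
    swing_time = swing_time,
    stance_time = stride_time - swing_time
  )
}

#' Spatial gait parameters from a reconstructed trajectory
#'
#' `stride_length_k` is the Euclidean norm of the ground-plane (x, y)
#' displacement between the stride's start and end positions; vertical
#' displacement is excluded under the level-walking convention (set
#' `use_3d = TRUE` for the full 3-D norm). `gait_velocity_k =
#' stride_length_k / stride_time_k` using the temporal parameters joined by
#' `stride_id`.
#'
#' @param traj a `trajectory` covering every stride (its `sample` column is
#'   matched against stride borders).
#' @param strides a min_vel stride list (borders at zero-velocity
#'   instants).
#' @param temporal output of [temporal_parameters()] for the same strides.
#' @param use_3d include the vertical axis in the stride-length norm.
#' @return a tibble with `stride_id`, `stride_time`, `swing_time`,
#'   `stance_time`, `stride_length` (m) and `gait_velocity` (m/s).
#' @export
spatial_parameters <- function(traj, strides, temporal = NULL,
                               use_3d = FALSE) {
  pos <- traj_pos(traj)
  lookup <- match(strides$start, traj$sample)
  lookup_end <- match(strides$end, traj$sample)
  if (anyNA(lookup) || anyNA(lookup_end)) {
    bad <- strides$stride_id[is.na(lookup) | is.na(lookup_end)][1]
    stop("trajectory does not cover stride ", bad)
  }
  d <- pos[lookup_end, , drop = FALSE] - pos[lookup, , drop = FALSE]
  stride_length <- unname(if (use_3d) sqrt(rowSums(d^2)) else
    sqrt(d[, 1]^2 + d[, 2]^2))
  out <- tibble::tibble(stride_id = strides$stride_id,
                        stride_length = stride_length)
  if (!is.null(temporal)) {
    out <- dplyr::left_join(temporal, out, by = "stride_id")
    out$gait_velocity <- out$stride_length / out$stride_time
  }
  out
}
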