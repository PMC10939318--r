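#' Detect gait events within segmented strides
#'
#' For each stride (toe-off-to-toe-off convention) three events are
#' extracted from the body-frame signals:
#'
#' * the swing peak is the argmax of `gyr_ml` inside the stride;
#' * `tc` (terminal contact / toe-off) is the sample of the last
#'   non-positive `gyr_ml` value before the swing peak, i.e. the
#'   negative-to-positive zero-crossing immediately preceding the dominant
#'   positive swing rotation;
#' * `ic` (initial contact / heel strike) is the argmin of `acc_pa` in the
#'   window `(swing peak, swing peak + ic_search_fraction * stride
#'   length]`, optionally after zero-phase Butterworth low-pass filtering
#'   of `acc_pa` (the "filtered" variant);
#' * `min_vel` (mid-stance) is the center of the `min_vel_window`-long
#'   window with minimal gyroscope-norm energy in `(ic, stride end]`.
#'
#' Strides where any rule fails (no sign change in `gyr_ml`, empty search
#' window) are flagged `detectable = FALSE` with `NA` events rather than
#' dropped.
#'
#' @param rec a body-frame `imu_recording`.
#' @param strides a stride list tibble (`stride_id`, `start`, `end`).
#' @param ic_search_fraction fraction of the stride length after the swing
#'   peak searched for `ic` (0 < f <= 1).
#' @param min_vel_window mid-stance energy window in seconds.
#' @param lowpass_cutoff low-pass cutoff in Hz for `acc_pa` before the `ic`
#'   search, or `NULL` for the unfiltered variant.
#' @param filter_order Butterworth filter order (applied forward-backward,
#'   so the effective order doubles and the phase is zero).
#' @return an event list tibble: `stride_id`, `start`, `end`, `tc`, `ic`,
#'   `min_vel` (absolute 0-based sample indices), `detectable`.
#' @export
detect_events <- function(rec, strides,
                          ic_search_fraction = 0.5,
                          min_vel_window = 0.1,
                          lowpass_cutoff = NULL,
                          filter_order = 2) {
  if (imu_frame(rec) != "body") stop("detect_events expects a body-frame recording")
  stopifnot(ic_search_fraction > 0, ic_search_fraction <= 1,
            min_vel_window > 0)
  rate <- sampling_rate(rec)
  gyr_ml <- rec$gyr_ml
  acc_pa <- rec$acc_pa
  if (!is.null(lowpass_cutoff)) {
    bf <- signal::butter(filter_order, lowpass_cutoff / (rate / 2),
                         type = "low")
    acc_pa <- as.numeric(signal::filtfilt(bf, acc_pa))
  }
  gnorm2 <- rowSums(gyr_matrix(rec)^2)
  w_mv <- max(1L, as.integer(round(min_vel_window * rate)))
  n <- nrow(rec)

  res <- purrr::pmap(strides[c("stride_id", "start", "end")],
                     function(stride_id, start, end) {
    na_row <- tibble::tibble(stride_id = stride_id, start = start,
                             end = end, tc = NA_integer_, ic = NA_integer_,
                             min_vel = NA_integer_, detectable = FALSE)
    seg <- gyr_ml[(start + 1):end]
    if (all(seg <= 0)) return(na_row)           # no positive swing peak
    peak <- start + which.max(seg) - 1L         # absolute 0-based index
    before <- gyr_ml[(start + 1):(peak + 1)]
    nonpos <- which(before <= 0)
    # crossing at or before the first stride sample: the stride border IS
    # the zero-crossing (segmented strides start at toe-off)
    tc <- if (length(nonpos) == 0) start else start + nonpos[length(nonpos)] - 1L
    # ic: argmin acc_pa in (peak, peak + f * stride_len], clipped
    hi <- min(end - 1L, peak + as.integer(floor(ic_search_fraction * (end - start))), n - 1L)
    if (hi <= peak) return(na_row)
    win <- acc_pa[(peak + 2):(hi + 1)]
    ic <- peak + which.min(win)
    # min_vel: center of the minimal-energy window in (ic, end]
    lo_mv <- ic + 1L
    hi_mv <- min(end, n)                        # exclusive end
    if (hi_mv - lo_mv < w_mv) return(na_row)
    e <- rolling_stat(gnorm2[(lo_mv + 1):hi_mv], w_mv, "mean")
    pos <- lo_mv + which.min(e) - 1L            # window start
    min_vel <- pos + w_mv %/% 2
    tibble::tibble(stride_id = stride_id, start = start, end = end,
                   tc = tc, ic = as.integer(ic),
                   min_vel = as.integer(min_vel), detectable = TRUE)
  })
  validate_event_list(dplyr::bind_rows(res))
}

#' Re-segment strides from mid-stance to mid-stance
#'
#' Trajectory reconstruction needs strides whose borders are zero-velocity
#' instants. This converts segmented (toe-off-to-toe-off) strides with
#' detected events into `min_vel` strides spanning
#' `[min_vel_k, min_vel_{k+1})`. Events are re-assigned to the new stride
#' containing them; the leading/trailing partial strides are dropped, so an
#' unbroken sequence of `n` strides yields `n - 1` min_vel strides.
#' Non-detectable strides split the sequence: no min_vel stride bridges the
#' gap.
#'
#' @param events event list from [detect_events()].
#' @return a list with `strides` (the min_vel stride list) and `events`
#'   (the re-assigned event list).
#' @export
to_min_vel_strides <- function(events) {
  ok <- events$detectable & !is.na(events$min_vel)
  if (sum(ok) < 2) {
    warning("fewer than 2 strides with a detectable min_vel event")
    empty <- event_list(integer(), integer(), integer(), integer(),
                        integer(), integer(), logical())
    return(list(strides = stride_list(), events = empty))
  }
  runs <- split(seq_len(nrow(events)), cumsum(!ok))
  out <- list()
  for (r in runs) {
    r <- r[ok[r]]
    if (length(r) < 2) next
    for (k in seq_len(length(r) - 1)) {
      i <- r[k]; j <- r[k + 1]
      out[[length(out) + 1]] <- tibble::tibble(
        start = events$min_vel[i], end = events$min_vel[j],
        tc = events$tc[j], ic = events$ic[j], min_vel = events$min_vel[i]
      )
    }
  }
  out <- dplyr::bind_rows(out)
  out <- out[order(out$start), ]
  ev <- event_list(seq_len(nrow(out)) - 1L, out$start, out$end,
                   out$tc, out$ic, out$min_vel, detectable = TRUE)
  list(strides = ev[c("stride_id", "start", "end")], events = ev)
}
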