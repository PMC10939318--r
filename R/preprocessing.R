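#' Detect static windows from the gyroscope norm
#'
#' Slides a window (1-sample hop) over the recording, computes a metric of
#' the per-sample gyroscope norm inside each window and marks windows whose
#' metric falls below `threshold`. Passing windows are merged into maximal
#' static regions.
#'
#' @param rec an `imu_recording` (any frame).
#' @param window_length window length in seconds.
#' @param metric one of `"mean"`, `"max"`, `"variance"` of the gyroscope
#'   norm within the window.
#' @param threshold threshold in deg/s (or (deg/s)^2 for `"variance"`);
#'   windows with metric strictly below it count as static.
#' @return an interval list of maximal static regions (0-based, half-open).
#' @export
find_static_windows <- function(rec, window_length = 0.1,
                                metric = c("mean", "max", "variance"),
                                threshold = 5) {
  metric <- match.arg(metric)
  stopifnot(window_length > 0, threshold >= 0)
  rate <- sampling_rate(rec)
  n <- nrow(rec)
  w <- max(1L, as.integer(round(window_length * rate)))
  if (w > n) stop("static window (", w, " samples) is longer than the recording")
  gnorm <- sqrt(rowSums(gyr_matrix(rec)^2))
  stat <- rolling_stat(gnorm, w, metric)
  pass <- which(stat < threshold)            # window start indices (1-based)
  if (length(pass) == 0) return(interval_list())
  merge_intervals(pass - 1L, pass - 1L + w)
}

# rolling statistic over windows [i, i + w) for i = 1 .. n - w + 1
rolling_stat <- function(x, w, metric) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  means <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  switch(metric,
    mean = means,
    max = {
      # simple rolling max; windows are short so this stays cheap
      vapply(seq_len(n - w + 1), function(i) max(x[i:(i + w - 1)]), 0)
    },
    variance = {
      cs2 <- c(0, cumsum(x^2))
      m2 <- (cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]) / w
      pmax(m2 - means^2, 0)
    }
  )
}

#' Align a recording with gravity
#'
#' Finds static regions (via [find_static_windows()]), pools all static
#' samples, and rotates the whole recording by the single shortest-arc
#' rotation that maps the mean static acceleration vector onto the gravity
#' target `(0, 0, 9.81)` m/s^2 (specific-force convention: a static, level
#' sensor reads +g along +z).
#'
#' The default static-window metric is the conservative `max` of the
#' gyroscope norm: windows that contain even single moving samples (whose
#' accelerations would skew the pooled gravity estimate badly) are
#' excluded entirely.
#'
#' @inheritParams find_static_windows
#' @param gravity gravity magnitude in m/s^2.
#' @return a list with elements `recording` (the rotated recording) and
#'   `rotation` (the unit quaternion that was applied).
#' @export
align_to_gravity <- function(rec, window_length = 0.1,
                             metric = c("max", "mean", "variance"),
                             threshold = 10, gravity = 9.81) {
  metric <- match.arg(metric)
  static <- find_static_windows(rec, window_length, metric, threshold)
  if (nrow(static) == 0) {
    stop("no static window found; rotate the recording manually or relax the threshold")
  }
  # pool only the interior of each static region: boundary samples can be
  # gyroscope-quiet while still decelerating (end of the heel-strike
  # transient), and even a few such samples bias the gravity estimate
  margin <- max(1L, as.integer(round(window_length * sampling_rate(rec) / 2)))
  lo <- static$start + margin
  hi <- static$end - margin
  keep <- lo < hi
  if (!any(keep)) { lo <- static$start; hi <- static$end; keep <- lo < hi }
  idx <- unlist(purrr::map2(lo[keep], hi[keep], ~ seq(.x + 1, .y)))
  acc <- acc_matrix(rec)
  mean_acc <- colMeans(acc[idx, , drop = FALSE])
  if (sqrt(sum(mean_acc^2)) < 0.5 * gravity) {
    stop("mean static acceleration norm is below 0.5 g; data look free-fall-like")
  }
  q <- quat_shortest_arc(mean_acc, c(0, 0, gravity))
  out <- rebuild_recording(rec,
    quat_rotate(q, acc), quat_rotate(q, gyr_matrix(rec)))
  list(recording = out, rotation = q)
}
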