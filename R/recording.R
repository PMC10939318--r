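#' Create an IMU recording
#'
#' An IMU recording is a tibble with one row per sample and six signal
#' columns, annotated with a sampling rate, a coordinate frame and (for the
#' body frame) a body side. Units follow the package-wide convention:
#' acceleration in m/s^2, angular velocity in deg/s.
#'
#' Column naming encodes the frame:
#' * sensor / world-aligned frame: `acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`
#' * body frame: `acc_pa, acc_ml, acc_si, gyr_pa, gyr_ml, gyr_si`
#'
#' In the sensor frame the x axis is expected to point roughly forward
#' (anterior), y to the left and z upward when the foot is flat. The body
#' frame axes are posterior->anterior (pa), medial->lateral (ml) and
#' superior->inferior (si); see [to_body_frame()].
#'
#' @param data data frame with the six signal columns (extra columns are
#'   kept).
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param frame one of `"sensor"`, `"body"`, `"world"`.
#' @param side one of `"left"`, `"right"`, `"n/a"`. Required (not `"n/a"`)
#'   when `frame = "body"`.
#' @return a tibble of class `imu_recording` with attributes
#'   `sampling_rate`, `frame`, `side`.
#' @examples
#' rec <- imu_recording(
#'   data.frame(acc_x = 0, acc_y = 0, acc_z = 9.81,
#'              gyr_x = 0, gyr_y = 0, gyr_z = 0)[rep(1, 100), ],
#'   sampling_rate = 100
#' )
#' @export
imu_recording <- function(data, sampling_rate,
                          frame = c("sensor", "body", "world"),
                          side = c("n/a", "left", "right")) {
  frame <- match.arg(frame)
  side <- match.arg(side)
  if (frame == "body" && side == "n/a") {
    stop("a body-frame recording requires side = 'left' or 'right'")
  }
  out <- tibble::as_tibble(data)
  cols <- imu_cols(frame)
  missing <- setdiff(cols, names(out))
  if (length(missing) > 0) {
    stop("missing signal columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(out) < 1) stop("recording must contain at least one sample")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  structure(out,
    sampling_rate = as.numeric(sampling_rate), frame = frame, side = side,
    class = c("imu_recording", class(tibble::tibble()))
  )
}

imu_cols <- function(frame) {
  if (frame == "body") {
    c("acc_pa", "acc_ml", "acc_si", "gyr_pa", "gyr_ml", "gyr_si")
  } else {
    c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  }
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "# IMU recording: %d samples @ %g Hz, frame = %s%s\n",
    nrow(x), attr(x, "sampling_rate"), attr(x, "frame"),
    if (attr(x, "side") != "n/a") paste0(" (", attr(x, "side"), ")") else ""
  ))
  NextMethod()
}

#' @rdname imu_recording
#' @param rec an `imu_recording`.
#' @export
sampling_rate <- function(rec) {
  r <- attr(rec, "sampling_rate")
  if (is.null(r)) stop("object has no sampling_rate attribute")
  r
}

imu_frame <- function(rec) attr(rec, "frame") %||% "sensor"
imu_side <- function(rec) attr(rec, "side") %||% "n/a"

# acc / gyr sample matrices (n x 3) regardless of frame
acc_matrix <- function(rec) {
  cols <- imu_cols(imu_frame(rec))[1:3]
  as.matrix(rec[, cols])
}
gyr_matrix <- function(rec) {
  cols <- imu_cols(imu_frame(rec))[4:6]
  as.matrix(rec[, cols])
}

# rebuild a recording from signal matrices, preserving metadata
rebuild_recording <- function(rec, acc, gyr, frame = imu_frame(rec),
                              side = imu_side(rec)) {
  cols <- imu_cols(frame)
  d <- tibble::as_tibble(cbind(acc, gyr), .name_repair = "minimal")
  names(d) <- cols
  imu_recording(d, sampling_rate(rec), frame = frame, side = side)
}

# body-frame axis maps (sensor -> body). pa = +x and si = -z on both sides;
# ml = +y (left) / -y (right) so the lateral direction follows ISB
# convention and left/right body frames are mirror images.
body_frame_matrix <- function(side) {
  switch(side,
    left  = diag(c(1, 1, -1)),   # (pa, ml, si) = (x,  y, -z), det = -1
    right = diag(c(1, -1, -1)),  # (pa, ml, si) = (x, -y, -z), det = +1
    stop("unknown side: ", side)
  )
}

#' Convert a sensor-frame recording to the body frame (and back)
#'
#' Relabels and re-signs the sensor axes to the anatomical body-frame axes
#' pa (posterior->anterior), ml (medial->lateral) and si
#' (superior->inferior). The left and right transforms are mirror images of
#' each other, so identical anatomical motion of either foot yields
#' identical body-frame signals.
#'
#' Acceleration transforms as an ordinary vector. Angular velocity is a
#' pseudovector: under the mirrored (determinant -1) axis map it picks up
#' an extra sign flip (`gyr_body = det(M) * M * gyr_sensor`), which is what
#' makes the mirror-image property hold for rotations as well.
#'
#' @param rec a sensor-frame `imu_recording` (x forward, y left, z up).
#' @param side `"left"` or `"right"`.
#' @return a body-frame `imu_recording` with columns
#'   `acc_pa, acc_ml, acc_si, gyr_pa, gyr_ml, gyr_si`. `to_sensor_frame()`
#'   inverts the conversion exactly.
#' @export
to_body_frame <- function(rec, side = c("left", "right")) {
  side <- match.arg(side)
  if (imu_frame(rec) != "sensor") {
    stop("to_body_frame expects a sensor-frame recording")
  }
  M <- body_frame_matrix(side)
  acc <- acc_matrix(rec) %*% t(M)
  gyr <- gyr_matrix(rec) %*% t(M) * det(M)
  rebuild_recording(rec, acc, gyr, frame = "body", side = side)
}

#' @rdname to_body_frame
#' @export
to_sensor_frame <- function(rec) {
  if (imu_frame(rec) != "body") stop("to_sensor_frame expects a body-frame recording")
  side <- imu_side(rec)
  M <- body_frame_matrix(side)
  Minv <- t(M)  # signed permutation: inverse = transpose
  acc <- acc_matrix(rec) %*% t(Minv)
  gyr <- gyr_matrix(rec) %*% t(Minv) * det(Minv)
  rebuild_recording(rec, acc, gyr, frame = "sensor", side = side)
}

#' Read an IMU recording from delimited text
#'
#' Expects a header with columns `acc_x, acc_y, acc_z, gyr_x, gyr_y, gyr_z`
#' (m/s^2 and deg/s).
#'
#' @param path CSV file path.
#' @param sampling_rate sampling rate in Hz.
#' @param frame,side frame annotation, see [imu_recording()].
#' @param ... passed to [utils::read.csv()].
#' @return an `imu_recording`.
#' @export
read_imu_csv <- function(path, sampling_rate, frame = "sensor",
                         side = "n/a", ...) {
  imu_recording(utils::read.csv(path, ...), sampling_rate,
                frame = frame, side = side)
}

#' @rdname read_imu_csv
#' @param rec recording to write.
#' @export
write_imu_csv <- function(rec, path) {
  utils::write.csv(as.data.frame(rec), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
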