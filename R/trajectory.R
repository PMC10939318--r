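#' Trajectory containers
#'
#' A trajectory is a tibble with one row per sample: an absolute 0-based
#' `sample` index, world-frame position columns `pos_x, pos_y, pos_z` (m)
#' and unit-quaternion orientation columns `q_x, q_y, q_z, q_w` (sensor to
#' world, active convention).
#'
#' @param sample integer sample indices (0-based).
#' @param pos n x 3 position matrix (m).
#' @param quat n x 4 quaternion matrix in (x, y, z, w) order.
#' @param rate sampling rate (Hz).
#' @return a tibble of class `trajectory`.
#' @export
trajectory <- function(sample, pos, quat, rate) {
  pos <- as.matrix(pos); quat <- as.matrix(quat)
  stopifnot(nrow(pos) == nrow(quat), length(sample) == nrow(pos))
  if (any(abs(quat_norm(quat) - 1) > 1e-6)) {
    stop("trajectory orientations must be unit quaternions")
  }
  out <- tibble::tibble(
    sample = as.integer(sample),
    pos_x = pos[, 1], pos_y = pos[, 2], pos_z = pos[, 3],
    q_x = quat[, 1], q_y = quat[, 2], q_z = quat[, 3], q_w = quat[, 4]
  )
  structure(out, sampling_rate = rate,
            class = c("trajectory", class(tibble::tibble())))
}

traj_pos <- function(traj) as.matrix(traj[, c("pos_x", "pos_y", "pos_z")])
traj_quat <- function(traj) as.matrix(traj[, c("q_x", "q_y", "q_z", "q_w")])

DEG2RAD <- pi / 180

# cumulative trapezoidal integral of an n x k matrix sampled at dt
cumtrapz_mat <- function(x, dt) {
  n <- nrow(x)
  if (n == 1) return(x * 0)
  inc <- (x[-1, , drop = FALSE] + x[-n, , drop = FALSE]) / 2 * dt
  rbind(0, apply(inc, 2, cumsum))
}

#' Orientation from gyroscope integration
#'
#' Propagates orientation by first-order quaternion exponential steps:
#' `q_{k+1} = q_k (x) dq(gyr_k * dt)` with `dq` built from the axis-angle
#' of the per-sample rotation. Gyroscope input is in deg/s and converted to
#' radians once, on entry. All outputs are unit-normalized.
#'
#' @param rec an `imu_recording`.
#' @param q0 initial orientation quaternion (sensor to world).
#' @return an n x 4 quaternion matrix (row k = orientation at sample k).
#' @export
integrate_gyro <- function(rec, q0 = quat_identity()) {
  gyr <- gyr_matrix(rec) * DEG2RAD
  dt <- 1 / sampling_rate(rec)
  n <- nrow(gyr)
  dq <- quat_from_rotvec(gyr * dt)
  if (n == 1) dq <- matrix(dq, nrow = 1)
  out <- matrix(0, n, 4, dimnames = list(NULL, c("q_x", "q_y", "q_z", "q_w")))
  q <- quat_normalize(q0)
  out[1, ] <- q
  if (n > 1) {
    for (k in 1:(n - 1)) {
      q <- quat_normalize(quat_multiply(q, dq[k, ]))
      out[k + 1, ] <- q
    }
  }
  out
}

#' Madgwick AHRS orientation filter (IMU form)
#'
#' Gyroscope quaternion-derivative propagation corrected by `beta` times
#' the normalized gradient of the accelerometer-gravity objective
#' `f(q) = R(q)^T (0,0,1) - acc/||acc||`. The correction is converted to an
#' equivalent angular-rate term so that the stepping scheme is identical to
#' [integrate_gyro()]; with `beta = 0` the two are bitwise equal. Samples
#' with zero-norm acceleration skip the gradient step (gyro-only).
#'
#' @inheritParams integrate_gyro
#' @param beta algorithm gain (rad/s), >= 0.
#' @return an n x 4 unit-quaternion matrix.
#' @export
madgwick <- function(rec, beta = 0.1, q0 = quat_identity()) {
  stopifnot(beta >= 0)
  gyr <- gyr_matrix(rec) * DEG2RAD
  acc <- acc_matrix(rec)
  dt <- 1 / sampling_rate(rec)
  n <- nrow(gyr)
  out <- matrix(0, n, 4, dimnames = list(NULL, c("q_x", "q_y", "q_z", "q_w")))
  q <- quat_normalize(q0)
  out[1, ] <- q
  if (n > 1) {
    for (k in 1:(n - 1)) {
      omega <- gyr[k, ]
      anorm <- sqrt(sum(acc[k, ]^2))
      if (beta > 0 && anorm > 0) {
        a <- acc[k, ] / anorm
        x <- q[1]; y <- q[2]; z <- q[3]; w <- q[4]
        f <- c(2 * (x * z - w * y) - a[1],
               2 * (w * x + y * z) - a[2],
               w^2 - x^2 - y^2 + z^2 - a[3])
        # J^T f with J = d(R^T e_z)/d(x,y,z,w)
        grad <- c(
          2 * z * f[1] + 2 * w * f[2] - 2 * x * f[3],
          -2 * w * f[1] + 2 * z * f[2] - 2 * y * f[3],
          2 * x * f[1] + 2 * y * f[2] + 2 * z * f[3],
          -2 * y * f[1] + 2 * x * f[2] + 2 * w * f[3]
        )
        gn <- sqrt(sum(grad^2))
        if (gn > 0) {
          qdot_c <- -beta * grad / gn            # (x, y, z, w) order
          werr <- 2 * quat_multiply(quat_conjugate(q), qdot_c)
          omega <- omega + werr[1:3]
        }
      }
      q <- quat_normalize(quat_multiply(q, quat_from_rotvec(omega * dt)))
      out[k + 1, ] <- q
    }
  }
  out
}

# world-frame linear (gravity-free) acceleration from a recording and an
# orientation series; acc input in m/s^2
world_linear_acc <- function(rec, orientations, gravity = 9.81) {
  aw <- quat_rotate(orientations, acc_matrix(rec))
  aw[, 3] <- aw[, 3] - gravity
  aw
}

slice_region <- function(region, n) {
  if (is.null(region)) return(c(0L, n))
  stopifnot(length(region) == 2, region[1] >= 0, region[2] <= n,
            region[1] < region[2])
  as.integer(region)
}

#' Dedrifted double integration: forward-backward scheme
#'
#' Integrates gravity-corrected world-frame acceleration over a region that
#' starts and ends at zero-velocity instants (e.g. a min_vel stride).
#' Velocity is integrated forward with `v(start) = 0` and backward with
#' `v(end) = 0`; the two estimates are blended with a sigmoid weight ramp,
#' which cancels drift that accumulates linearly over the region. Vertical
#' position is linearly detrended so `z(end) = z(start)` (level-walking
#' assumption).
#'
#' @param rec an `imu_recording` (world-consistent acceleration after
#'   gravity alignment).
#' @param orientations n x 4 quaternion matrix for the full recording.
#' @param region `c(start, end)` 0-based half-open sample interval, or
#'   `NULL` for the whole recording.
#' @param gravity gravity magnitude (m/s^2).
#' @param steepness sigmoid steepness of the blending ramp.
#' @return a `trajectory` covering the region, starting at the origin.
#' @export
forward_backward_integration <- function(rec, orientations, region = NULL,
                                         gravity = 9.81, steepness = 10) {
  region <- slice_region(region, nrow(rec))
  idx <- (region[1] + 1):region[2]
  m <- length(idx)
  if (m < 3) stop("integration region must span at least 3 samples")
  dt <- 1 / sampling_rate(rec)
  q <- orientations[idx, , drop = FALSE]
  aw <- world_linear_acc(rec, orientations, gravity)[idx, , drop = FALSE]
  vf <- cumtrapz_mat(aw, dt)                       # v(start) = 0
  vb_rev <- cumtrapz_mat(aw[m:1, , drop = FALSE], dt)
  vb <- -vb_rev[m:1, , drop = FALSE]               # v(end) = 0
  s <- seq(0, 1, length.out = m)
  w <- 1 / (1 + exp(-steepness * (s - 0.5)))
  v <- (1 - w) * vf + w * vb
  p <- cumtrapz_mat(v, dt)
  p[, 3] <- p[, 3] - s * (p[m, 3] - p[1, 3])       # level-walking detrend
  trajectory(idx - 1L, p, q, sampling_rate(rec))
}

#' Dedrifted double integration: piecewise-linear drift model
#'
#' Integrates world-frame linear acceleration to velocity, then removes a
#' drift series that equals the measured velocity at each ZUPT-region
#' midpoint, is linearly interpolated between midpoints and held constant
#' outside the first/last midpoint. Velocity is clamped to exactly zero
#' inside ZUPT regions before integrating to position. A constant
#' accelerometer bias produces linearly growing velocity drift, which this
#' model removes exactly between ZUPTs.
#'
#' @inheritParams forward_backward_integration
#' @param zupts interval list of zero-velocity regions (>= 2 required).
#' @return a `trajectory` for the whole recording, starting at the origin.
#' @export
piecewise_linear_dedrifted_integration <- function(rec, orientations, zupts,
                                                   gravity = 9.81) {
  if (nrow(zupts) < 2) {
    stop("need >= 2 ZUPT regions; use forward_backward_integration for single-region data")
  }
  n <- nrow(rec)
  dt <- 1 / sampling_rate(rec)
  aw <- world_linear_acc(rec, orientations, gravity)
  v_raw <- cumtrapz_mat(aw, dt)
  mid <- floor((zupts$start + zupts$end) / 2)       # 0-based midpoints
  drift <- vapply(1:3, function(c3) {
    stats::approx(x = mid, y = v_raw[mid + 1, c3], xout = 0:(n - 1),
                  rule = 2)$y
  }, numeric(n))
  v <- v_raw - drift
  zmask <- interval_mask(zupts, n)
  v[zmask, ] <- 0
  p <- cumtrapz_mat(v, dt)
  trajectory(0:(n - 1), p, orientations, sampling_rate(rec))
}

# logical mask of samples covered by an interval list
interval_mask <- function(intervals, n) {
  mask <- logical(n)
  for (i in seq_len(nrow(intervals))) {
    mask[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  }
  mask
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

#' ZUPT-aided error-state Kalman filter with RTS smoothing
#'
#' Reconstructs the foot trajectory over a whole recording. A nominal
#' strapdown trajectory (gyroscope quaternion integration; velocity and
#' position by trapezoidal integration of gravity-corrected world
#' acceleration) is tracked by a 9-dimensional error state
#' `(dp, dv, dtheta)` with transition
#' `[[I, I dt, 0], [0, I, -skew(R acc) dt], [0, 0, I]]` (world-side
#' multiplicative orientation error). At every sample inside a ZUPT region
#' a velocity-is-zero pseudo-measurement updates the error state. The error
#' state is accumulated (not injected) during the forward pass; a
#' Rauch-Tung-Striebel backward pass with gain
#' `C_k = P_k F_k^T P_pred,k+1^{-1}` smooths the error trajectory, which is
#' then injected into the nominal trajectory once per sample
#' (`p + dp`, `v + dv`, `dq(dtheta) (x) q`).
#'
#' @param rec an `imu_recording` whose acceleration is gravity-consistent
#'   with `gravity` (run [align_to_gravity()] first if needed).
#' @param zupts interval list of zero-velocity regions.
#' @param accel_noise accelerometer process-noise density (m/s^2 per
#'   sqrt(s)).
#' @param gyro_noise gyroscope process-noise density (deg/s per sqrt(s));
#'   converted to radians internally.
#' @param zupt_measurement_noise ZUPT pseudo-measurement noise (m/s).
#' @param initial_covariance 9 diagonal entries of the initial error
#'   covariance (p, v, theta blocks).
#' @param gravity gravity magnitude (m/s^2).
#' @param q0,p0 initial orientation and position.
#' @return an object of class `kalman_result`: a list with `trajectory`
#'   (smoothed), `filtered` (forward-only trajectory), `velocity` (smoothed
#'   n x 3), `cov_trace_filtered` and `cov_trace_smoothed` (per-sample
#'   traces of the error covariance), and `zupts`.
#' @export
rts_kalman <- function(rec, zupts,
                       accel_noise = 0.05, gyro_noise = 0.05,
                       zupt_measurement_noise = 0.01,
                       initial_covariance = rep(c(1e-6, 1e-6, 1e-4), each = 3),
                       gravity = 9.81,
                       q0 = quat_identity(), p0 = c(0, 0, 0)) {
  stopifnot(accel_noise > 0, gyro_noise > 0, zupt_measurement_noise > 0,
            length(initial_covariance) == 9)
  n <- nrow(rec)
  dt <- 1 / sampling_rate(rec)
  rate <- sampling_rate(rec)
  gyro_noise_rad <- gyro_noise * DEG2RAD

  # nominal strapdown
  qs <- integrate_gyro(rec, q0)
  aw <- world_linear_acc(rec, qs, gravity)
  v_nom <- cumtrapz_mat(aw, dt)
  p_nom <- cumtrapz_mat(v_nom, dt) +
    matrix(p0, n, 3, byrow = TRUE)

  zmask <- interval_mask(zupts, n)
  if (!zmask[1]) {
    warning("no ZUPT at the start of the recording; initial velocity assumed zero")
  }

  # specific force rotated to world, for the attitude-velocity coupling
  f_w <- quat_rotate(qs, acc_matrix(rec))

  # tiny position process noise keeps the predicted covariance invertible
  # for the RTS gain without affecting the estimates measurably
  Q <- diag(c(rep(1e-12 * dt, 3), rep(accel_noise^2 * dt, 3),
              rep(gyro_noise_rad^2 * dt, 3)))
  I9 <- diag(9)
  H <- cbind(matrix(0, 3, 3), diag(3), matrix(0, 3, 3))
  Rm <- diag(zupt_measurement_noise^2, 3)

  dx_filt <- matrix(0, 9, n)
  dx_pred <- matrix(0, 9, n)
  P_filt <- array(0, c(9, 9, n))
  P_pred <- array(0, c(9, 9, n))
  P <- diag(initial_covariance)
  dx <- numeric(9)
  P_filt[, , 1] <- P
  P_pred[, , 1] <- P

  make_F <- function(k) {
    F <- I9
    F[1:3, 4:6] <- diag(dt, 3)
    F[4:6, 7:9] <- -skew3(f_w[k, ]) * dt
    F
  }

  for (k in seq_len(n - 1)) {
    F <- make_F(k)
    dx <- F %*% dx
    P <- F %*% P %*% t(F) + Q
    P <- (P + t(P)) / 2
    dx_pred[, k + 1] <- dx
    P_pred[, , k + 1] <- P
    if (zmask[k + 1]) {
      y <- -v_nom[k + 1, ] - dx[4:6]
      S <- P[4:6, 4:6] + Rm
      K <- P[, 4:6] %*% solve(S)
      dx <- dx + K %*% y
      IKH <- I9 - K %*% H
      P <- IKH %*% P %*% t(IKH) + K %*% Rm %*% t(K)
      P <- (P + t(P)) / 2
    }
    if (!all(is.finite(P))) {
      stop("non-finite covariance at sample ", k + 1)
    }
    dx_filt[, k + 1] <- dx
    P_filt[, , k + 1] <- P
  }

  # RTS backward pass
  dx_s <- dx_filt
  P_s <- P_filt
  for (k in seq(n - 1, 1)) {
    F <- make_F(k)
    C <- P_filt[, , k] %*% t(F) %*% solve(P_pred[, , k + 1])
    dx_s[, k] <- dx_filt[, k] +
      C %*% (dx_s[, k + 1] - dx_pred[, k + 1])
    Pk <- P_filt[, , k] +
      C %*% (P_s[, , k + 1] - P_pred[, , k + 1]) %*% t(C)
    P_s[, , k] <- (Pk + t(Pk)) / 2
  }

  inject <- function(dx_mat) {
    dp <- t(dx_mat[1:3, , drop = FALSE])
    dv <- t(dx_mat[4:6, , drop = FALSE])
    dth <- t(dx_mat[7:9, , drop = FALSE])
    qc <- quat_normalize(quat_multiply(quat_from_rotvec(dth), qs))
    list(p = p_nom + dp, v = v_nom + dv, q = qc)
  }
  sm <- inject(dx_s)
  fi <- inject(dx_filt)

  structure(list(
    trajectory = trajectory(0:(n - 1), sm$p, sm$q, rate),
    filtered = trajectory(0:(n - 1), fi$p, fi$q, rate),
    velocity = sm$v,
    velocity_filtered = fi$v,
    cov_trace_filtered = apply(P_filt, 3, function(m) sum(diag(m))),
    cov_trace_smoothed = apply(P_s, 3, function(m) sum(diag(m))),
    zupts = zupts
  ), class = "kalman_result")
}

#' @export
print.kalman_result <- function(x, ...) {
  cat(sprintf(
    "# RTS Kalman trajectory: %d samples, %d ZUPT regions\n",
    nrow(x$trajectory), nrow(x$zupts)))
  invisible(x)
}
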