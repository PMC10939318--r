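#' Gait simulation profiles
#'
#' A `gait_profile` collects every knob of the synthetic gait generator.
#' The defaults describe unhurried level walking of a healthy adult
#' recorded at 204.8 Hz: 1.3 m strides of 1.1 s with 60% stance, a 5 cm
#' swing clearance arc and a ~35 degree sagittal dorsiflexion sweep.
#'
#' @param n_strides number of strides per bout.
#' @param stride_length forward displacement per stride (m).
#' @param stride_time stride duration (s); rounded to whole samples, the
#'   realized value is `round(stride_time * sampling_rate) /
#'   sampling_rate`.
#' @param stance_fraction fraction of the stride spent in stance (0-1).
#' @param foot_clearance peak vertical foot lift during swing (m).
#' @param pitch_range amplitude of the sagittal dorsiflexion arc (deg).
#' @param sampling_rate sampling rate (Hz).
#' @param acc_noise_sigma,gyro_noise_sigma additive white Gaussian noise
#'   levels for the synthetic IMU (m/s^2, deg/s).
#' @param gyro_bias constant gyroscope bias added to all three axes
#'   (deg/s).
#' @param seed integer seed making noisy output reproducible; `NULL` uses
#'   the current RNG state.
#' @param side which foot the virtual sensor is mounted on.
#' @param lead_in initial quiet-standing duration (s); the session ends
#'   flush with the final stance.
#' @param n_bouts,rest_duration walking bouts per session and
#'   quiet-standing rest between bouts (s); `profile_4x10m()` is a 4-bout
#'   preset emulating a 4 x 10 m walk test (straight bouts, turns
#'   omitted).
#' @param impact_duration duration of the terminal swing braking pulse
#'   emulating the heel-strike impact transient (s).
#' @param rise_fraction fraction of swing spent accelerating the foot
#'   forward.
#' @return a list of class `gait_profile`.
#' @export
gait_profile <- function(n_strides = 10, stride_length = 1.3,
                         stride_time = 1.1, stance_fraction = 0.6,
                         foot_clearance = 0.05, pitch_range = 35,
                         sampling_rate = 204.8,
                         acc_noise_sigma = 0, gyro_noise_sigma = 0,
                         gyro_bias = 0, seed = NULL,
                         side = "left", lead_in = 2,
                         n_bouts = 1, rest_duration = 2,
                         impact_duration = 0.014, rise_fraction = 0.45) {
  stopifnot(n_strides >= 1, stride_length > 0, stride_time > 0,
            stance_fraction > 0, stance_fraction < 1,
            foot_clearance >= 0, pitch_range >= 0, sampling_rate > 0,
            acc_noise_sigma >= 0, gyro_noise_sigma >= 0,
            lead_in > 0, n_bouts >= 1, rest_duration >= 0,
            impact_duration > 0, rise_fraction > 0, rise_fraction < 1)
  structure(as.list(environment()), class = "gait_profile")
}

#' @rdname gait_profile
#' @param ... overrides passed to [gait_profile()].
#' @export
profile_4x10m <- function(...) {
  gait_profile(n_strides = 8, n_bouts = 4, rest_duration = 2, ...)
}

# quintic smoothstep: C^2 ramp 0 -> 1 on [0, 1]
smoothstep5 <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

#' Simulate a ground-truth gait trajectory
#'
#' Builds the kinematic ground truth of a walking session: per stride
#' (toe-off-to-toe-off convention: swing followed by stance) the foot
#' advances `stride_length` with a C^2 minimum-jerk-style forward velocity
#' profile ending in a short braking pulse (the heel-strike transient),
#' lifts along a smooth clearance arc peaking at `foot_clearance`, and
#' pitches through a single smooth dorsiflexion arc of amplitude
#' `pitch_range`. During stance the foot is exactly stationary and level.
#' Heading is constant (straight-line walking; turns are not simulated).
#'
#' Ground truth: `tc` at the stance-to-swing transition (= stride start),
#' `ic` at the swing-to-stance transition, `min_vel` at the stance
#' midpoint; ZUPT regions coincide exactly with stance (plus lead-in and
#' inter-bout rests).
#'
#' @param profile a [gait_profile()].
#' @return a list with `trajectory` (truth [trajectory()]), `strides`,
#'   `events`, `zupts` (tibbles) and `parameters` (per-stride truth).
#' @export
simulate_trajectory <- function(profile) {
  p <- profile
  rate <- p$sampling_rate
  n_stride <- as.integer(round(p$stride_time * rate))
  n_swing <- as.integer(round((1 - p$stance_fraction) * n_stride))
  n_stance <- n_stride - n_swing
  stopifnot(n_swing >= 8, n_stance >= 2)
  lead_n <- as.integer(round(p$lead_in * rate))
  rest_n <- as.integer(round(p$rest_duration * rate))

  # absolute stride start samples, with rests between bouts
  starts <- integer(0)
  pos0 <- lead_n
  for (b in seq_len(p$n_bouts)) {
    starts <- c(starts, pos0 + (seq_len(p$n_strides) - 1L) * n_stride)
    pos0 <- pos0 + p$n_strides * n_stride
    if (b < p$n_bouts) pos0 <- pos0 + rest_n
  }
  n <- pos0  # session ends flush with the final stance
  n_total_strides <- length(starts)

  # swing phase grids (shared by all strides)
  s <- (0:n_swing) / n_swing                     # phase incl. touchdown
  w_f <- p$impact_duration / (n_swing / rate)    # brake fraction of swing
  # the brake completes ~3/4 sample before touchdown so that the
  # central-difference velocity at the touchdown sample is already ~0,
  # keeping the touchdown sample consistent with a zero-velocity update
  pad <- 0.75 / n_swing
  v_shape <- smoothstep5(s / p$rise_fraction) *
    smoothstep5((1 - pad - s) / w_f)
  inc <- (v_shape[-1] + v_shape[-length(v_shape)]) / 2
  X <- c(0, cumsum(inc)) / sum(inc)              # displacement 0 -> 1
  Z <- sin(pi * s)^4                             # clearance arc, C^2
  TH <- -p$pitch_range * DEG2RAD * sin(pi * s)^2 # dorsiflexion dip

  x <- numeric(n); z <- numeric(n); th <- numeric(n)
  x_base <- 0
  for (k in seq_len(n_total_strides)) {
    b0 <- starts[k]
    idx <- b0 + 0:n_swing                        # 0-based, incl. touchdown
    x[idx + 1] <- x_base + p$stride_length * X
    z[idx + 1] <- p$foot_clearance * Z
    th[idx + 1] <- TH
    x_base <- x_base + p$stride_length
    # stance (and any following rest) keeps the touchdown pose
    nxt <- if (k < n_total_strides) starts[k + 1] else n
    if (b0 + n_swing + 1 < nxt) {
      x[(b0 + n_swing + 2):nxt] <- x_base
    }
  }

  quats <- quat_from_rotvec(cbind(0, th, 0))
  traj <- trajectory(0:(n - 1), cbind(x, 0, z), quats, rate)

  strides <- stride_list(starts, starts + n_stride)
  events <- event_list(
    stride_id = strides$stride_id,
    start = strides$start, end = strides$end,
    tc = starts, ic = starts + n_swing,
    min_vel = starts + n_swing + n_stance %/% 2,
    detectable = TRUE
  )
  # true ZUPT regions: every sample outside a swing phase is static. The
  # touchdown sample itself carries the tail of the impact transient (its
  # central-difference velocity is not yet zero), so stance starts one
  # sample after ic.
  swing_mask <- logical(n)
  for (b0 in starts) swing_mask[(b0 + 1):(b0 + n_swing + 1)] <- TRUE
  r <- rle(!swing_mask)
  ends_cum <- cumsum(r$lengths)
  static_runs <- which(r$values)
  zupts <- interval_list(ends_cum[static_runs] - r$lengths[static_runs],
                         ends_cum[static_runs])

  realized_stride_time <- n_stride / rate
  parameters <- tibble::tibble(
    stride_id = strides$stride_id,
    stride_time = realized_stride_time,
    swing_time = n_swing / rate,
    stance_time = n_stance / rate,
    stride_length = p$stride_length,
    gait_velocity = p$stride_length / realized_stride_time
  )
  list(trajectory = traj, strides = strides, events = events,
       zupts = zupts, parameters = parameters)
}

#' Synthesize IMU signals from a trajectory (inverse strapdown)
#'
#' World-frame acceleration is obtained from central second differences of
#' position; the sensor-frame specific force is
#' `acc = R(q)^T (a_world + (0, 0, g))` and the gyroscope reading comes
#' from per-sample relative quaternions converted to deg/s. This
#' discretization is exactly consistent with the package's strapdown
#' integrators (trapezoidal velocity/position, first-order quaternion
#' exponential), so noise-free round trips reproduce the input trajectory
#' to discretization accuracy. Optional additive white Gaussian noise and
#' a constant gyroscope bias are seeded via the profile.
#'
#' @param traj a [trajectory()] as produced by [simulate_trajectory()].
#' @param profile the matching [gait_profile()] (noise, bias, seed, rate).
#' @param gravity gravity magnitude (m/s^2).
#' @return a sensor-frame `imu_recording`.
#' @export
trajectory_to_imu <- function(traj, profile, gravity = 9.81) {
  n <- nrow(traj)
  if (n < 3) stop("trajectory must span at least 3 samples")
  rate <- attr(traj, "sampling_rate")
  dt <- 1 / rate
  pos <- traj_pos(traj)
  qs <- traj_quat(traj)

  aw <- matrix(0, n, 3)
  aw[2:(n - 1), ] <- (pos[3:n, ] - 2 * pos[2:(n - 1), ] + pos[1:(n - 2), ]) / dt^2
  aw[1, ] <- aw[2, ]
  aw[n, ] <- aw[n - 1, ]
  aw[, 3] <- aw[, 3] + gravity
  acc <- quat_rotate(quat_conjugate(qs), aw)

  # body rates from relative quaternions q_k^-1 (x) q_{k+1}
  dq <- quat_multiply(quat_conjugate(qs[-n, , drop = FALSE]),
                      qs[-1, , drop = FALSE])
  gyr <- rbind(quat_to_rotvec(dq) / dt, c(0, 0, 0)) / DEG2RAD

  if (profile$acc_noise_sigma > 0 || profile$gyro_noise_sigma > 0 ||
      profile$gyro_bias != 0) {
    add_noise <- function() {
      if (profile$acc_noise_sigma > 0) {
        acc <<- acc + matrix(stats::rnorm(3 * n, 0, profile$acc_noise_sigma), n, 3)
      }
      if (profile$gyro_noise_sigma > 0) {
        gyr <<- gyr + matrix(stats::rnorm(3 * n, 0, profile$gyro_noise_sigma), n, 3)
      }
      gyr <<- gyr + profile$gyro_bias
    }
    if (!is.null(profile$seed)) {
      withr::with_seed(as.integer(profile$seed), add_noise())
    } else {
      add_noise()
    }
  }

  d <- tibble::tibble(
    acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
    gyr_x = gyr[, 1], gyr_y = gyr[, 2], gyr_z = gyr[, 3]
  )
  imu_recording(d, rate, frame = "sensor", side = "n/a")
}

#' Simulate a complete gait session with ground truth
#'
#' Composes [simulate_trajectory()] and [trajectory_to_imu()] into a
#' ground-truth bundle tying the synthetic recording to its true strides,
#' events, ZUPT regions, trajectory and per-stride parameters.
#'
#' @inheritParams simulate_trajectory
#' @param gravity gravity magnitude (m/s^2).
#' @return an object of class `gait_bundle`: list with `recording`,
#'   `trajectory`, `strides`, `events`, `zupts`, `parameters`, `profile`.
#' @export
simulate_session <- function(profile = gait_profile(), gravity = 9.81) {
  truth <- simulate_trajectory(profile)
  rec <- trajectory_to_imu(truth$trajectory, profile, gravity)
  structure(c(list(recording = rec), truth, list(profile = profile)),
            class = "gait_bundle")
}

#' @export
print.gait_bundle <- function(x, ...) {
  cat(sprintf(
    "# synthetic gait session: %d strides, %d samples @ %g Hz (%s foot)\n",
    nrow(x$strides), nrow(x$recording), x$profile$sampling_rate,
    x$profile$side))
  invisible(x)
}
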