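# Orientation estimation and signal conditioning.
#
# The complementary filter is a quaternion error-state formulation:
# orientation is propagated by exact gyroscope integration and corrected by
# proportional feedback terms computed from the normalized accelerometer
# (gravity direction, gain k1, 1/s) and magnetometer (heading, gain k2, 1/s).
# Initial orientation comes from an accelerometer/magnetometer TRIAD over the
# first still second, so there is no gyroscope drift at t = 0.

# quaternion utilities; q = (w, x, y, z), body -> world
quat_mul <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_rotvec <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(c(1, v / 2))
  c(cos(ang / 2), sin(ang / 2) * v / ang)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  q / sqrt(sum(q^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Remove the static gyroscope bias
#'
#' Subtracts the per-axis mean angular velocity measured over an initial
#' still window from the whole gyroscope stream; acceleration and magnetic
#' field are untouched.
#'
#' @param rec An [imu_recording()].
#' @param still_window Integer sample indices of the still period, at the
#'   start of the recording; at least 100 samples.
#' @param still_sd_threshold Stillness check: if any axis SD over the window
#'   exceeds this (rad/s; default 2 deg/s), a warning reports the measured SD.
#' @return The bias-corrected [imu_recording()].
#' @export
remove_gyro_bias <- function(rec, still_window = 1:1000,
                             still_sd_threshold = 2 * pi / 180) {
  stopifnot(inherits(rec, "imu_recording"))
  if (length(still_window) < 100)
    stop("too short window: the still window must span at least 100 samples",
         call. = FALSE)
  if (min(still_window) != 1L || max(still_window) > length(rec$t))
    stop("`still_window` must lie at the start of the recording", call. = FALSE)
  sds <- apply(rec$gyro[still_window, , drop = FALSE], 2, stats::sd)
  if (any(sds > still_sd_threshold))
    warning(sprintf("stillness check failed: gyro SD (rad/s) = %s",
                    paste(signif(sds, 3), collapse = ", ")), call. = FALSE)
  bias <- colMeans(rec$gyro[still_window, , drop = FALSE])
  out <- rec
  out$gyro <- sweep(rec$gyro, 2, bias, "-")
  out
}

#' Estimate sensor orientation with a complementary filter
#'
#' Propagates a body-to-world quaternion by gyroscope integration with
#' proportional error feedback: the gravity-direction error from the
#' normalized accelerometer is weighted by `k1` and the heading error from
#' the magnetometer by `k2` (both 1/s). The initial orientation and the
#' magnetic reference come from a TRIAD over the initial still window.
#'
#' @param rec A bias-corrected [imu_recording()].
#' @param k1 Accelerometer (gravity) feedback gain, 1/s.
#' @param k2 Magnetometer (heading) feedback gain, 1/s.
#' @param init_window Sample indices used for the static initialisation;
#'   defaults to the first second.
#' @return An `orientation_series`: `pitch_y` (deg, rotation about the sensor
#'   Y axis relative to the initial posture, positive flexion), `global_acc`
#'   (N x 3, m/s^2, vertically aligned inertial frame; gravity included as
#'   (0,0,g)), quaternions, gains, `fs` and the sensor location.
#' @export
estimate_orientation <- function(rec, k1 = 2.33, k2 = 7.44,
                                 init_window = NULL) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- length(rec$t)
  fs <- rec$fs
  dt <- 1 / fs
  if (is.null(init_window)) init_window <- seq_len(min(n, round(fs)))
  acc0 <- colMeans(rec$acc[init_window, , drop = FALSE])
  if (abs(sqrt(sum(acc0^2)) - GRAVITY) > 0.5 * GRAVITY)
    stop("initialisation error: accelerometer norm deviates more than 50% from g",
         call. = FALSE)
  mag0 <- colMeans(rec$mag[init_window, , drop = FALSE])

  z_b <- acc0 / sqrt(sum(acc0^2))                 # world up, in body axes
  m0 <- mag0 / sqrt(sum(mag0^2))
  m_h <- m0 - sum(m0 * z_b) * z_b                 # horizontal field component
  if (sqrt(sum(m_h^2)) < 1e-6)
    stop("initialisation error: magnetic field parallel to gravity", call. = FALSE)
  x_b <- m_h / sqrt(sum(m_h^2))                   # world magnetic north
  y_b <- cross3(z_b, x_b)
  R <- rbind(x_b, y_b, z_b, deparse.level = 0)    # body -> world
  q <- matrix_to_quat(R)
  R_init <- R
  m_w <- as.numeric(R %*% m0)                     # world-frame field reference
  m_w <- m_w / sqrt(sum(m_w^2))

  pitch <- numeric(n)
  gacc <- matrix(0, n, 3)
  quats <- matrix(0, n, 4)
  R <- quat_to_matrix(q)
  for (i in seq_len(n)) {
    a <- rec$acc[i, ]
    an <- sqrt(sum(a^2))
    e <- c(0, 0, 0)
    if (an > 1e-6) e <- e + k1 * cross3(a / an, R[3, ])
    m <- rec$mag[i, ]
    mn <- sqrt(sum(m^2))
    if (mn > 1e-6) {
      v_m <- as.numeric(crossprod(R, m_w))        # predicted field direction
      e_m <- cross3(m / mn, v_m)
      # heading-only correction: project on the vertical so the magnetometer
      # never disturbs the gravity-referenced inclination
      e <- e + k2 * sum(e_m * R[3, ]) * R[3, ]
    }
    omega <- rec$gyro[i, ] + e
    q <- quat_mul(q, quat_from_rotvec(omega * dt))
    q <- q / sqrt(sum(q^2))
    quats[i, ] <- q
    R <- quat_to_matrix(q)                        # post-update orientation
    gacc[i, ] <- R %*% a
    P <- crossprod(R_init, R)                     # rotation initial -> current
    pitch[i] <- atan2(P[1, 3] - P[3, 1], P[1, 1] + P[3, 3]) * 180 / pi
  }
  structure(list(pitch_y = pitch, global_acc = gacc, quat = quats,
                 k1 = k1, k2 = k2, fs = fs, location = rec$location),
            class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %s, %d samples @ %g Hz (k1 = %g, k2 = %g)\n",
              x$location, length(x$pitch_y), x$fs, x$k1, x$k2))
  invisible(x)
}

#' Tibia pitch angle
#'
#' Returns the fused rotation about the sensor Y axis relative to the initial
#' still posture, in degrees, with knee flexion (tibia inclining forward)
#' positive. For sensors mounted with the Y axis inverted, set `flip = TRUE`
#' to recover the same positive-flexion convention.
#'
#' @param series An `orientation_series` from a tibia-mounted recording.
#' @param flip Logical; negate the angle for an inverted mounting.
#' @return Numeric vector of pitch angles, degrees.
#' @export
tibia_pitch <- function(series, flip = FALSE) {
  stopifnot(inherits(series, "orientation_series"))
  if (!identical(series$location, "tibia"))
    stop("wrong sensor: tibia pitch requires a tibia-mounted recording",
         call. = FALSE)
  if (flip) -series$pitch_y else series$pitch_y
}
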