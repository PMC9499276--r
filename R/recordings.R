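#' IMU recording container
#'
#' Bundles the synchronised tri-axial streams of one magneto-inertial unit
#' (MIMU): linear acceleration, angular velocity and magnetic field, together
#' with the time base, sampling rate and anatomical mounting location. The
#' sensor x-axis is assumed to lie along the longitudinal axis of the
#' instrumented segment; all streams are in SI units (m/s^2, rad/s, uT).
#'
#' @param t Numeric vector of time stamps in seconds, strictly increasing.
#' @param acc N x 3 matrix of linear acceleration (m/s^2), body frame.
#' @param gyro N x 3 matrix of angular velocity (rad/s), body frame.
#' @param mag N x 3 matrix of magnetic field (uT), body frame.
#' @param fs Sampling rate in Hz.
#' @param location Mounting site, `"tibia"` or `"foot"`.
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(t, acc, gyro, mag, fs, location = c("tibia", "foot")) {
  location <- match.arg(location)
  acc <- as.matrix(acc); gyro <- as.matrix(gyro); mag <- as.matrix(mag)
  n <- length(t)
  if (ncol(acc) != 3L || ncol(gyro) != 3L || ncol(mag) != 3L)
    stop("acc, gyro and mag must each have 3 columns", call. = FALSE)
  if (nrow(acc) != n || nrow(gyro) != n || nrow(mag) != n)
    stop("all streams must have the same number of samples as `t`", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  if (n > 1L && any(diff(t) <= 0))
    stop("time stamps must be strictly increasing", call. = FALSE)
  g <- 9.80665
  if (any(abs(acc) > 16 * g + 1e-9))
    stop("acceleration exceeds the +/-16 g full-range scale", call. = FALSE)
  if (any(abs(gyro) > 2000 * pi / 180 + 1e-9))
    stop("angular velocity exceeds the +/-2000 deg/s full-range scale", call. = FALSE)
  structure(
    list(t = as.numeric(t), acc = unname(acc), gyro = unname(gyro),
         mag = unname(mag), fs = fs, location = location),
    class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s sensor, %d samples @ %g Hz (%.2f s)\n",
              x$location, length(x$t), x$fs, diff(range(x$t))))
  invisible(x)
}

#' Vertical ground-reaction-force recording
#'
#' Single vertical force-plate channel sampled during a countermovement jump,
#' with the body mass the athlete loads onto the plate during quiet standing.
#'
#' @param t Time stamps in seconds.
#' @param grfv Vertical ground reaction force in newtons, non-negative.
#' @param fs Sampling rate in Hz (force plates here run at 1000 Hz).
#' @param body_mass Supported body mass in kg.
#' @return An object of class `grf_recording`.
#' @export
grf_recording <- function(t, grfv, fs, body_mass) {
  if (length(t) != length(grfv))
    stop("`t` and `grfv` must have the same length", call. = FALSE)
  if (any(grfv < 0)) stop("`grfv` must be non-negative", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive", call. = FALSE)
  if (!is.numeric(body_mass) || body_mass <= 0)
    stop("`body_mass` must be positive", call. = FALSE)
  structure(list(t = as.numeric(t), grfv = as.numeric(grfv), fs = fs,
                 body_mass = body_mass),
            class = "grf_recording")
}

#' @export
print.grf_recording <- function(x, ...) {
  cat(sprintf("<grf_recording> %d samples @ %g Hz, body mass %.1f kg\n",
              length(x$t), x$fs, x$body_mass))
  invisible(x)
}

#' Detected (or ground-truth) task events
#'
#' Sample indices of the instants that delimit each motor task: squat start,
#' end of the eccentric phase and squat end for the SLS; take-off and landing
#' instants plus 100 ms post-landing risk windows for the CHT; end of the
#' unweighting phase and flight start for the CMJ.
#'
#' @param task `"SLS"`, `"CHT"` or `"CMJ"`.
#' @param fs Sampling rate of the segmented signal, Hz.
#' @param ... Named event fields, depending on the task: `i_start`, `i_epe`,
#'   `i_end` (SLS); `to`, `la`, `risk_windows` (CHT); `i_unweight_end`,
#'   `i_flight_start` (CMJ).
#' @return An object of class `task_events`.
#' @export
task_events <- function(task = c("SLS", "CHT", "CMJ"), fs, ...) {
  task <- match.arg(task)
  ev <- list(...)
  needed <- switch(task,
    SLS = c("i_start", "i_epe", "i_end"),
    CHT = c("to", "la", "risk_windows"),
    CMJ = c("i_unweight_end", "i_flight_start"))
  missing_f <- setdiff(needed, names(ev))
  if (length(missing_f))
    stop("missing event fields: ", paste(missing_f, collapse = ", "), call. = FALSE)
  if (task == "SLS" && !(ev$i_start < ev$i_epe && ev$i_epe < ev$i_end))
    stop("SLS events must satisfy i_start < i_epe < i_end", call. = FALSE)
  if (task == "CHT") {
    if (length(ev$to) != length(ev$la))
      stop("take-off and landing counts differ", call. = FALSE)
    if (any(ev$to >= ev$la))
      stop("each take-off must precede its landing", call. = FALSE)
  }
  if (task == "CMJ" && ev$i_unweight_end >= ev$i_flight_start)
    stop("unweight end must precede flight start", call. = FALSE)
  structure(c(list(task = task, fs = fs), ev), class = "task_events")
}

#' @export
print.task_events <- function(x, ...) {
  cat(sprintf("<task_events> %s @ %g Hz\n", x$task, x$fs))
  if (x$task == "SLS")
    cat(sprintf("  start %d  eccentric end %d  end %d\n", x$i_start, x$i_epe, x$i_end))
  if (x$task == "CHT")
    cat(sprintf("  %d hops; TO: %s; LA: %s\n", length(x$to),
                paste(x$to, collapse = ","), paste(x$la, collapse = ",")))
  if (x$task == "CMJ")
    cat(sprintf("  unweight end %d  flight start %d\n",
                x$i_unweight_end, x$i_flight_start))
  invisible(x)
}

#' Serialise task events to JSON
#'
#' Writes sample indices together with their time equivalents in seconds so
#' that segmentations can be audited alongside feature tables.
#'
#' @param ev A [task_events()] object.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
task_events_json <- function(ev, path = NULL) {
  stopifnot(inherits(ev, "task_events"))
  idx <- ev[setdiff(names(ev), c("task", "fs", "risk_windows"))]
  out <- list(task = ev$task, fs = ev$fs,
              samples = idx,
              seconds = lapply(idx, function(i) (i - 1) / ev$fs))
  if (!is.null(ev$risk_windows)) out$risk_windows <- ev$risk_windows
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
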