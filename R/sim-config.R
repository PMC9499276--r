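# Standard gravity used throughout (m/s^2).
GRAVITY <- 9.80665

#' Simulation configuration
#'
#' Collects the sensor, noise and cohort-variance settings used by the
#' synthetic-signal generators. Defaults reproduce the acquisition set-up the
#' pipeline targets: MIMUs at 500 Hz, force plates at 1000 Hz, three trials
#' per condition, and sensor noise levels typical of consumer MEMS parts in
#' the +/-16 g / +/-2000 deg/s class.
#'
#' @param sampling_rate_imu IMU sampling rate, Hz.
#' @param sampling_rate_grf Force-plate sampling rate, Hz.
#' @param gyro_bias Length-3 constant gyroscope bias, rad/s.
#' @param noise_sd_acc Accelerometer white-noise SD, m/s^2.
#' @param noise_sd_gyro Gyroscope white-noise SD, rad/s.
#' @param noise_sd_mag Magnetometer white-noise SD, uT.
#' @param noise_sd_grf Force-plate noise SD, N.
#' @param n_subjects Number of simulated subjects (cohort generator).
#' @param n_trials Trials per subject and condition; at least 2 for
#'   reliability use.
#' @param between_subject_sd Named numeric vector: between-subject SD per
#'   parameter (cohort generator).
#' @param within_subject_sd Named numeric vector: within-subject
#'   (trial-to-trial) SD per parameter.
#' @param seed Integer seed; every generator draws from an RNG seeded from
#'   this value (plus any per-call seed), never from the global state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate_imu = 500,
                       sampling_rate_grf = 1000,
                       gyro_bias = c(0.01, -0.02, 0.005),
                       noise_sd_acc = 0.05,
                       noise_sd_gyro = 0.0035,
                       noise_sd_mag = 0.5,
                       noise_sd_grf = 2,
                       n_subjects = 17,
                       n_trials = 3,
                       between_subject_sd = NULL,
                       within_subject_sd = NULL,
                       seed = 1L) {
  if (sampling_rate_imu <= 0 || sampling_rate_grf <= 0)
    stop("sampling rates must be positive", call. = FALSE)
  if (length(gyro_bias) != 3L)
    stop("`gyro_bias` must have length 3", call. = FALSE)
  for (nm in c("noise_sd_acc", "noise_sd_gyro", "noise_sd_mag", "noise_sd_grf")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("`", nm, "` must be a single non-negative number", call. = FALSE)
  }
  if (n_trials < 2)
    stop("`n_trials` must be at least 2 for reliability use", call. = FALSE)
  if (n_subjects < 1) stop("`n_subjects` must be at least 1", call. = FALSE)
  structure(list(
    sampling_rate_imu = sampling_rate_imu,
    sampling_rate_grf = sampling_rate_grf,
    gyro_bias = as.numeric(gyro_bias),
    noise_sd_acc = noise_sd_acc,
    noise_sd_gyro = noise_sd_gyro,
    noise_sd_mag = noise_sd_mag,
    noise_sd_grf = noise_sd_grf,
    n_subjects = as.integer(n_subjects),
    n_trials = as.integer(n_trials),
    between_subject_sd = between_subject_sd,
    within_subject_sd = within_subject_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> imu %g Hz, grf %g Hz, %d subjects x %d trials, ",
                     "seed %d\n  noise SD: acc %g m/s^2, gyro %g rad/s, mag %g uT, ",
                     "grf %g N\n"),
              x$sampling_rate_imu, x$sampling_rate_grf, x$n_subjects, x$n_trials,
              x$seed, x$noise_sd_acc, x$noise_sd_gyro, x$noise_sd_mag, x$noise_sd_grf))
  invisible(x)
}

#' Ground truth attached to a simulated recording
#'
#' @param event_times Named list/vector of event times in seconds, strictly
#'   increasing within a task.
#' @param true_parameter_values Named list of the parameter values implied by
#'   the generator's analytic trajectories.
#' @param true_icc True intraclass correlation (cohort generator only).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(event_times, true_parameter_values = list(),
                         true_icc = NA_real_) {
  ev <- unlist(event_times)
  if (length(ev) > 1L && any(diff(ev) <= 0))
    stop("ground-truth event times must be strictly increasing", call. = FALSE)
  if (!is.na(true_icc) && (true_icc < 0 || true_icc > 1))
    stop("`true_icc` must lie in [0, 1]", call. = FALSE)
  structure(list(event_times = as.list(ev),
                 true_parameter_values = true_parameter_values,
                 true_icc = true_icc), class = "ground_truth")
}

# Evaluate `expr` under a locally seeded RNG without touching global state.
local_seeded <- function(seed, expr) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}
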