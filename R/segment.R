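# Task segmentation: squat phases on the tibia pitch angle, hop take-offs and
# landings on foot angular-velocity / jerk thresholds, jump unweighting and
# flight onset on the vertical GRF.

#' Trailing moving standard deviation
#'
#' Element `i` is the sample SD of `x` over the trailing window ending at
#' `i`; the first `window - 1` elements are filled with the first valid
#' value.
#'
#' @param x Numeric signal.
#' @param window Window length in samples, at least 2.
#' @return Numeric vector, same length as `x`.
#' @export
moving_sd <- function(x, window) {
  if (window < 2) stop("`window` must be at least 2", call. = FALSE)
  if (window > length(x)) stop("`window` exceeds the signal length", call. = FALSE)
  out <- zoo::rollapplyr(x, window, stats::sd, fill = NA)
  out[seq_len(window - 1L)] <- out[window]
  out
}

# centered moving average with sane edge handling
smooth_ma <- function(x, width_samples) {
  m <- max(1L, as.integer(round(width_samples)))
  if (m %% 2L == 0L) m <- m + 1L
  if (m == 1L || m > length(x)) return(x)
  out <- zoo::rollmean(x, m, fill = NA)
  half <- (m - 1L) %/% 2L
  out[seq_len(half)] <- out[half + 1L]
  n <- length(x)
  out[(n - half + 1L):n] <- out[n - half]
  out
}

# central-difference time derivative, per second
central_diff <- function(x, fs) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  d[1] <- d[2]; d[n] <- d[n - 1]
  d
}

#' Segment a single leg squat from the tibia pitch angle
#'
#' The movement start is the first instant at which the 10-sample moving SD
#' of the pitch angle, scaled by `sigma_scale`, exceeds `start_factor` times
#' the static SD of the first `static_samples` samples. The eccentric-phase
#' end is the maximum of the pitch curve, and the squat end the first
#' subsequent return of the angle to its start value (within a tolerance
#' band of `start_factor` static SDs).
#'
#' @param pitch Tibia pitch angle, degrees.
#' @param fs Sampling rate, Hz.
#' @param static_samples Samples defining the static reference SD.
#' @param window Moving-SD window, samples.
#' @param start_factor Threshold multiplier on the static SD.
#' @param sigma_scale Scaling applied to the moving SD before comparison.
#' @param scale_both_sides If `TRUE`, `sigma_scale` is applied to both sides
#'   of the comparison (making it presentation-only).
#' @param return_band Absolute tolerance (deg) for the return to the start
#'   angle; defaults to the same sensitivity as the start rule,
#'   `start_factor / sigma_scale` times the static SD.
#' @param min_run_s Minimum time the start rule must stay satisfied for a
#'   candidate to count as movement onset (noise transients do not persist;
#'   a squat does), s. The reported start is the beginning of the run.
#' @return A [task_events()] with `i_start`, `i_epe`, `i_end`.
#' @export
segment_sls <- function(pitch, fs, static_samples = 1000, window = 10,
                        start_factor = 2, sigma_scale = 10,
                        scale_both_sides = FALSE, return_band = NULL,
                        min_run_s = 0.05) {
  if (length(pitch) < static_samples)
    stop("signal shorter than the static reference window", call. = FALSE)
  sd_static <- stats::sd(pitch[seq_len(static_samples)])
  sig <- moving_sd(pitch, window) * sigma_scale
  thr <- start_factor * sd_static * if (scale_both_sides) sigma_scale else 1
  ex <- sig > thr
  ex[seq_len(max(window - 1L, static_samples))] <- FALSE
  need <- max(1L, as.integer(round(min_run_s * fs)))
  runs <- rle(ex)
  ends <- cumsum(runs$lengths)
  k <- which(runs$values & runs$lengths >= need)
  if (!length(k))
    stop("no movement: the moving-SD start rule never fires", call. = FALSE)
  i_start <- ends[k[1]] - runs$lengths[k[1]] + 1L
  i_epe <- which.max(pitch)
  if (i_epe <= i_start)
    stop("no movement: pitch maximum precedes the detected start", call. = FALSE)
  band <- if (is.null(return_band)) start_factor * sd_static / sigma_scale else
    return_band
  after <- which(pitch[(i_epe + 1L):length(pitch)] <= pitch[i_start] + band)
  if (!length(after)) {
    warning("unterminated task: pitch never returns to its start value",
            call. = FALSE)
    i_end <- length(pitch)
  } else {
    i_end <- i_epe + after[1]
  }
  task_events("SLS", fs, i_start = i_start, i_epe = i_epe, i_end = i_end)
}

#' Segment a crossover hop test
#'
#' Take-offs are the instants at which the time derivative of the smoothed
#' foot angular-velocity magnitude first falls below `to_threshold`
#' (rad/s^2); each landing is the first local maximum of the derivative of
#' the smoothed acceleration magnitude exceeding `la_threshold` (m/s^3)
#' after the take-off. Events alternate under a refractory period, and a
#' 100 ms risk window is attached after each landing.
#'
#' @param foot_rec Bias-corrected foot [imu_recording()].
#' @param foot_orient Optional `orientation_series`; detection operates on
#'   frame-invariant signal magnitudes so it is not required.
#' @param to_threshold Take-off threshold on d|gyro|/dt, rad/s^2.
#' @param la_threshold Landing threshold on d|acc|/dt, m/s^3.
#' @param t_risk Risk-window duration after landing, s.
#' @param refractory Dead time after each detected event, s.
#' @param smooth_s Width of the centered moving average applied to the
#'   magnitude signals before differentiation, s.
#' @return A [task_events()] with `to`, `la` and `risk_windows`.
#' @export
segment_cht <- function(foot_rec, foot_orient = NULL, to_threshold = -0.6,
                        la_threshold = 7, t_risk = 0.1, refractory = 0.2,
                        smooth_s = 0.08) {
  stopifnot(inherits(foot_rec, "imu_recording"))
  fs <- foot_rec$fs
  n <- length(foot_rec$t)
  gn <- smooth_ma(sqrt(rowSums(foot_rec$gyro^2)), smooth_s * fs)
  an <- smooth_ma(sqrt(rowSums(foot_rec$acc^2)), smooth_s * fs)
  dg <- central_diff(gn, fs)
  ja <- central_diff(an, fs)
  refr <- as.integer(round(refractory * fs))

  to <- integer(0); la <- integer(0)
  pos <- 1L
  repeat {
    cand <- which(dg[pos:n] < to_threshold)
    if (!length(cand)) break
    i_to <- pos + cand[1] - 1L
    to <- c(to, i_to)
    from <- min(i_to + 1L, n)
    idx <- from:(n - 1L)
    is_max <- ja[idx] > la_threshold &
      ja[idx] > ja[idx - 1L] & ja[idx] >= ja[idx + 1L]
    if (!any(is_max)) {
      stop(sprintf(paste0("unbalanced events: %d take-off(s) at [%s] but only ",
                          "%d landing(s) at [%s]"),
                   length(to), paste(to, collapse = ", "),
                   length(la), paste(la, collapse = ", ")), call. = FALSE)
    }
    i_la <- idx[which(is_max)[1]]
    la <- c(la, i_la)
    pos <- i_la + refr
    if (pos >= n) break
  }
  if (!length(to))
    stop("no movement: no take-off threshold crossing found", call. = FALSE)

  w <- as.integer(round(t_risk * fs))
  risk <- lapply(la, function(i) {
    end <- i + w - 1L
    if (end > n) {
      warning("risk window truncated at the end of the recording", call. = FALSE)
      end <- n
    }
    c(start = i, end = end)
  })
  task_events("CHT", fs, to = to, la = la, risk_windows = risk)
}

#' Segment a countermovement jump from the vertical GRF
#'
#' Body weight is measured over the initial quiet standing. The end of the
#' unweighting phase is the first inflection of the (smoothed) GRF after the
#' force drops below body weight by `onset_band`; the flight start is the
#' first sample at or below `flight_threshold`. The net vertical force (GRF
#' minus body weight) over the segmented window is returned alongside.
#'
#' @param grf A [grf_recording()].
#' @param onset_band Unweighting-onset band below body weight, N.
#' @param flight_threshold Force level treated as "zero" for flight, N.
#' @param smooth_s Moving-average width and second-derivative stencil, s.
#' @param quiet_s Quiet-standing duration used to measure body weight, s.
#' @return List with `events` ([task_events()]), `net_force` (N, over
#'   `[i_unweight_end, i_flight_start)`) and `body_weight` (N).
#' @export
segment_cmj <- function(grf, onset_band = 20, flight_threshold = 5,
                        smooth_s = 0.04, quiet_s = 0.5) {
  stopifnot(inherits(grf, "grf_recording"))
  fs <- grf$fs
  n <- length(grf$grfv)
  bw <- mean(grf$grfv[seq_len(round(quiet_s * fs))])
  i_flight <- which(grf$grfv <= flight_threshold)
  if (!length(i_flight))
    stop("no flight: GRF never reaches the flight threshold", call. = FALSE)
  i_flight <- i_flight[1]

  f <- smooth_ma(grf$grfv, smooth_s * fs)
  onset <- which(f < bw - onset_band)
  if (!length(onset) || onset[1] >= i_flight)
    stop("no unweighting dip before flight", call. = FALSE)
  onset <- onset[1]
  k <- max(2L, as.integer(round(smooth_s * fs)))
  idx <- (k + 1L):(n - k)
  d2 <- (f[idx + k] - 2 * f[idx] + f[idx - k]) * (fs / k)^2
  rel <- which(idx >= onset & d2 >= 0)
  if (!length(rel))
    stop("no inflection found after the unweighting onset", call. = FALSE)
  i_unweight <- idx[rel[1]]
  if (i_unweight >= i_flight)
    stop("inflection found only after flight start", call. = FALSE)

  ev <- task_events("CMJ", fs, i_unweight_end = i_unweight,
                    i_flight_start = i_flight)
  seg <- i_unweight:(i_flight - 1L)
  list(events = ev, net_force = grf$grfv[seg] - bw, body_weight = bw)
}
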