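# Synthetic MIMU / force-plate signal generators.
#
# Each generator builds a deterministic, analytically known clean trajectory,
# rotates gravity and the earth magnetic field into the moving sensor frame,
# then adds the configured gyroscope bias and white sensor noise. Ground-truth
# event times and parameter values are carried alongside so every downstream
# detector and feature extractor can be verified against the construction.

# World-frame constants shared by the generators.
EARTH_MAG <- c(22, 0, -41)           # uT, horizontal-north + downward dip

# Rotation by `theta` (rad) about the sensor Y axis.
rot_y <- function(theta) {
  c_ <- cos(theta); s_ <- sin(theta)
  matrix(c(c_, 0, s_, 0, 1, 0, -s_, 0, c_), 3, 3, byrow = TRUE)
}

# Initial tibia orientation: sensor x along the (vertical) shank, y mediolateral.
# Columns are the body axes expressed in the world frame.
R0_TIBIA <- matrix(c(0, 0, -1,
                     0, 1, 0,
                     1, 0, 0), 3, 3, byrow = TRUE)

# Slow multi-sine oscillation emulating postural sway; unit-amplitude shape.
sway_wave <- function(t, freqs, phases) {
  out <- numeric(length(t))
  for (j in seq_along(freqs)) out <- out + sin(2 * pi * freqs[j] * t + phases[j])
  out / length(freqs)
}

add_imu_noise <- function(acc, gyro, mag, config) {
  n <- nrow(acc)
  if (config$noise_sd_acc > 0)
    acc <- acc + matrix(stats::rnorm(3 * n, 0, config$noise_sd_acc), n, 3)
  gyro <- sweep(gyro, 2, config$gyro_bias, "+")
  if (config$noise_sd_gyro > 0)
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, config$noise_sd_gyro), n, 3)
  if (config$noise_sd_mag > 0)
    mag <- mag + matrix(stats::rnorm(3 * n, 0, config$noise_sd_mag), n, 3)
  list(acc = acc, gyro = gyro, mag = mag)
}

#' Simulate a single leg squat trial
#'
#' Generates tibia- and foot-mounted MIMU streams for one single leg squat:
#' a still bipodal phase, an eccentric descent of the tibia pitch angle to a
#' peak flexion, a faster concentric return that overshoots the start value
#' by a small hyperextension before settling. The descent starts with a small
#' non-zero angular velocity (a decisive movement initiation) and the return
#' crosses the initial angle with non-zero velocity, so that threshold-based
#' segmentation has well-defined instants to find. Postural sway is injected
#' as low-frequency translational acceleration on the transverse (y-z) axes,
#' smaller during quiet bipodal stance than during the squat itself.
#'
#' @param config A [sim_config()].
#' @param subject_scale Dimensionless scaling of the movement amplitude
#'   (peak flexion and sway), emulating between-subject differences.
#' @param seed Integer seed for this trial's noise draws.
#' @param peak_flexion_deg Peak of the tibia pitch excursion, degrees.
#' @param t_still Still standing time before movement, s (must cover at
#'   least 1000 samples for the static-threshold rule downstream).
#' @param t_ecc,t_return,t_settle Durations of the eccentric descent, the
#'   concentric return and the final settling, s.
#' @param overshoot_deg Hyperextension overshoot below the start angle at the
#'   end of the return, degrees.
#' @param sway_scale Dimensionless multiplier on the postural-sway
#'   accelerations (0 simulates a perfectly steady subject).
#' @return A list with elements `tibia` and `foot` ([imu_recording()]) and
#'   `truth` ([ground_truth()] with `sls_start`, `epe`, `sls_end` times).
#' @export
simulate_sls <- function(config, subject_scale = 1, seed = config$seed,
                         peak_flexion_deg = 75, t_still = 3,
                         t_ecc = 2.2, t_return = 1.2, t_settle = 1.2,
                         overshoot_deg = 4, sway_scale = 1) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_imu
  if (t_still * fs < 1000)
    stop("invalid config: still period must cover at least 1000 samples",
         call. = FALSE)
  P <- peak_flexion_deg * subject_scale
  dlt <- overshoot_deg
  w_kick <- 0.35                        # linear onset fraction (~12 deg/s kick)
  v_ret <- 12                           # initial return speed, deg/s
  b <- v_ret * t_return / (P + dlt)

  t_tail <- 0.5
  t_tot <- t_still + t_ecc + t_return + t_settle + t_tail
  n <- floor(t_tot * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  # analytic pitch profile (deg) and its derivative (deg/s)
  theta <- numeric(n); dtheta <- numeric(n)
  ph_d <- t >= t_still & t < t_still + t_ecc
  x <- (t[ph_d] - t_still) / t_ecc
  theta[ph_d] <- P * ((1 - w_kick) * (1 - cos(pi * x)) / 2 + w_kick * x)
  dtheta[ph_d] <- P / t_ecc * ((1 - w_kick) * pi / 2 * sin(pi * x) + w_kick)
  t_r0 <- t_still + t_ecc
  ph_r <- t >= t_r0 & t < t_r0 + t_return
  x <- (t[ph_r] - t_r0) / t_return
  cx <- (2 * x^3 - 3 * x^2 + 1) - b * (x^3 - 2 * x^2 + x)
  theta[ph_r] <- -dlt + (P + dlt) * cx
  dtheta[ph_r] <- (P + dlt) / t_return *
    (6 * x^2 - 6 * x - b * (3 * x^2 - 4 * x + 1))
  t_s0 <- t_r0 + t_return
  ph_s <- t >= t_s0 & t < t_s0 + t_settle
  x <- (t[ph_s] - t_s0) / t_settle
  theta[ph_s] <- -dlt * (1 + cos(pi * x)) / 2
  dtheta[ph_s] <- dlt * pi / (2 * t_settle) * sin(pi * x)

  # ground-truth instant at which the return crosses the initial angle
  cross_fn <- function(x) (2 * x^3 - 3 * x^2 + 1) - b * (x^3 - 2 * x^2 + x) -
    dlt / (P + dlt)
  x_cross <- stats::uniroot(cross_fn, c(0.5, 1), tol = 1e-12)$root
  truth <- ground_truth(
    event_times = list(sls_start = t_still,
                       epe = t_still + t_ecc,
                       sls_end = t_r0 + x_cross * t_return),
    true_parameter_values = list(T_tot = t_ecc, peak_flexion_deg = P))

  th_rad <- theta * pi / 180
  local_seeded(seed, {
    # quiet-stance sway is slow and small; during the squat, balance
    # corrections are larger and sit in the 1-4 Hz band, with the
    # mediolateral (y) knee wobble dominating the transverse plane
    env <- sway_scale * subject_scale *
      pmax(0, pmin(1, (t - t_still) / 0.3)) *
      pmax(0, pmin(1, (t_s0 + t_settle - t) / 0.3))
    f_slow <- c(0.24, 0.37, 0.53, 0.74, 0.98, 1.31)
    sway_y <- 0.07 * sway_scale * sway_wave(t, f_slow, stats::runif(6, 0, 2 * pi)) +
      0.55 * env * sway_wave(t, c(1.3, 2.1, 3.4), stats::runif(3, 0, 2 * pi))
    sway_z <- 0.07 * sway_scale * sway_wave(t, f_slow * 1.07, stats::runif(6, 0, 2 * pi)) +
      0.09 * env * sway_wave(t, c(1.5, 2.4, 3.1), stats::runif(3, 0, 2 * pi))

    acc_t <- cbind(GRAVITY * cos(th_rad), sway_y, GRAVITY * sin(th_rad) + sway_z)
    gyro_t <- cbind(0, dtheta * pi / 180, 0)
    v <- as.numeric(t(R0_TIBIA) %*% EARTH_MAG)
    mag_t <- cbind(cos(th_rad) * v[1] - sin(th_rad) * v[3], v[2],
                   sin(th_rad) * v[1] + cos(th_rad) * v[3])
    s_t <- add_imu_noise(acc_t, gyro_t, mag_t, config)

    foot_sway <- 0.02 * sway_scale * cbind(
      sway_wave(t, c(0.43, 0.61), stats::runif(2, 0, 2 * pi)),
      sway_wave(t, c(0.39, 0.57), stats::runif(2, 0, 2 * pi)))
    acc_f <- cbind(foot_sway[, 1], foot_sway[, 2], GRAVITY + 0)
    s_f <- add_imu_noise(acc_f, matrix(0, n, 3),
                         matrix(EARTH_MAG, n, 3, byrow = TRUE), config)

    list(tibia = imu_recording(t, s_t$acc, s_t$gyro, s_t$mag, fs, "tibia"),
         foot = imu_recording(t, s_f$acc, s_f$gyro, s_f$mag, fs, "foot"),
         truth = truth)
  })
}

#' Simulate a crossover hop trial
#'
#' Builds foot- and tibia-mounted MIMU streams for a triple single-leg hop.
#' The foot angular-velocity magnitude carries, for each hop, a symmetric
#' "tent" peaking exactly at take-off (so its time derivative first crosses
#' the take-off threshold at the true instant) and a fast-decaying rotation
#' burst at landing. The foot acceleration magnitude is near zero in flight
#' (free fall), carries a sharp impact-loading envelope after each landing
#' and a push-off hump that returns to zero exactly at take-off.
#'
#' @param config A [sim_config()].
#' @param hop_params List with `flight_s` (3 flight durations, s) and
#'   `contact_s` (2 ground-contact durations between hops, s).
#' @param seed Integer seed for this trial's noise draws.
#' @param omega_peak_to Angular-velocity tent peak at take-off, rad/s.
#' @param omega_peak_la Landing rotation-burst amplitude, rad/s.
#' @param acc_peak_la Peak of the landing impact-loading envelope, m/s^2.
#' @param t_still Initial still standing time, s.
#' @return List with `foot`, `tibia` ([imu_recording()]) and `truth`
#'   ([ground_truth()] with `to1..to3`, `la1..la3` times and the configured
#'   second-hop flight/contact durations plus clean risk-window peaks).
#' @export
simulate_cht <- function(config,
                         hop_params = list(flight_s = c(0.3, 0.3, 0.3),
                                           contact_s = c(0.4, 0.4)),
                         seed = config$seed,
                         omega_peak_to = 4.5, omega_peak_la = 22,
                         acc_peak_la = 153, t_still = 2.5) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$sampling_rate_imu
  fl <- hop_params$flight_s; ct <- hop_params$contact_s
  if (length(fl) != 3L || length(ct) != 2L)
    stop("invalid config: need 3 flight and 2 contact durations", call. = FALSE)
  if (any(c(fl, ct) <= 0))
    stop("invalid config: hop durations must be positive", call. = FALSE)
  if (t_still * fs < 1000)
    stop("invalid config: still period must cover at least 1000 samples",
         call. = FALSE)

  t_tent <- 0.15                        # tent half-duration around take-off
  tau_r <- 0.012; tau_d <- 0.325        # impact envelope rise / decay, s
  tau_wr <- 0.004; tau_wd <- 0.022      # landing rotation burst rise / decay, s
  to <- numeric(3); la <- numeric(3)
  to[1] <- t_still + 0.4
  la[1] <- to[1] + fl[1]
  to[2] <- la[1] + ct[1]; la[2] <- to[2] + fl[2]
  to[3] <- la[2] + ct[2]; la[3] <- to[3] + fl[3]
  t_tot <- la[3] + 1.2
  n <- floor(t_tot * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  # |omega| profile: take-off tents + landing bursts
  wn <- numeric(n)
  slope <- omega_peak_to / t_tent
  for (i in 1:3) {
    seg <- abs(t - to[i]) < t_tent
    wn[seg] <- pmax(wn[seg], omega_peak_to - slope * abs(t[seg] - to[i]))
    s <- t - la[i]
    seg <- s >= 0 & s < 0.25
    wn[seg] <- wn[seg] +
      omega_peak_la * (1 - exp(-s[seg] / tau_wr)) * exp(-s[seg] / tau_wd)
  }

  # |acc| profile: stance plateau at g tapering to zero at take-off, free-fall
  # flight, impact loading after landing
  an <- numeric(n)
  an[t < to[1]] <- GRAVITY
  taper <- t >= to[1] - 0.1 & t < to[1]
  an[taper] <- GRAVITY * (1 + cos(pi * (t[taper] - to[1] + 0.1) / 0.1)) / 2
  push_amp <- 15
  for (i in 1:3) {
    contact_end <- if (i < 3) to[i + 1] else la[3] + 0.8
    s <- t - la[i]
    in_contact <- s >= 0 & t < contact_end
    imp <- acc_peak_la * (1 - exp(-s / tau_r)) * exp(-s / tau_d)
    hmax <- contact_end - la[i]
    h <- pmin(1, pmax(0, (s - 0.15) / pmax(hmax - 0.15, 1e-9)))
    an[in_contact] <- (imp * (1 + cos(pi * h)) / 2)[in_contact] +
      GRAVITY * pmin(1, s[in_contact] / 0.1) *
        (if (i == 3) 1 else (1 + cos(pi * pmin(1, pmax(0, (s[in_contact] - 0.05) / (hmax - 0.05))))) / 2)
    if (i < 3) {
      ps <- t - (to[i + 1] - 0.16)
      seg <- ps >= 0 & ps < 0.16
      an[seg] <- an[seg] + push_amp * sin(pi * ps[seg] / 0.16)^2 *
        (1 - pmin(1, pmax(0, (t[seg] - to[i + 1] + 0.02) / 0.02)))
      an[t >= to[i + 1] & t < la[i + 1]] <- 0
    }
  }
  # force exact free fall in flight and exact zero at each take-off instant
  for (i in 1:3) an[t >= to[i] & t < la[i]] <- 0

  risk <- function(x, i0) {
    win <- t >= la[i0] & t < la[i0] + 0.1
    max(x[win])
  }
  truth <- ground_truth(
    event_times = list(to1 = to[1], la1 = la[1], to2 = to[2], la2 = la[2],
                       to3 = to[3], la3 = la[3]),
    true_parameter_values = list(
      FT = fl[2], CT = ct[2], T_tot = la[3] - to[1],
      wpeak_foot = risk(wn, 2) * 180 / pi,
      apeak_foot = risk(an, 2)))

  u_w <- c(0.45, 0.78, 0.4366); u_w <- u_w / sqrt(sum(u_w^2))
  local_seeded(seed, {
    gyro_f <- outer(wn, u_w)
    acc_f <- cbind(0.04 * sway_wave(t, c(0.5, 0.9), stats::runif(2, 0, 2 * pi)),
                   0.04 * sway_wave(t, c(0.6, 1.1), stats::runif(2, 0, 2 * pi)),
                   an)
    mag_f <- matrix(EARTH_MAG, n, 3, byrow = TRUE)
    s_f <- add_imu_noise(acc_f, gyro_f, mag_f, config)

    u_t <- c(0.3, 0.87, 0.39); u_t <- u_t / sqrt(sum(u_t^2))
    gyro_t <- outer(0.55 * wn, u_t)
    # tibia axial channel: half-amplitude copy of the foot loading profile,
    # clipped from below at gravity while the foot is grounded pre-trial
    acc_t <- cbind(pmax(0.55 * an, GRAVITY * (t < to[1])),
                   0.04 * sway_wave(t, c(0.45, 0.8), stats::runif(2, 0, 2 * pi)),
                   0.04 * sway_wave(t, c(0.55, 1.0), stats::runif(2, 0, 2 * pi)))
    s_t <- add_imu_noise(acc_t, gyro_t, mag_f, config)

    list(foot = imu_recording(t, s_f$acc, s_f$gyro, s_f$mag, fs, "foot"),
         tibia = imu_recording(t, s_t$acc, s_t$gyro, s_t$mag, fs, "tibia"),
         truth = truth)
  })
}

#' Simulate a countermovement-jump vertical GRF trace
#'
#' Builds the vertical ground-reaction force of a countermovement jump from
#' analytic centre-of-mass acceleration phases: quiet standing at body
#' weight, a gentle unweighting dip (sin^2 acceleration pulse, whose first
#' GRF inflection at a quarter of the dip duration defines the ground-truth
#' unweighting end), a sinusoidal propulsion pulse whose amplitude is solved
#' so the net impulse yields the requested jump height, and a zero-force
#' flight phase. The GRF reaches exactly zero at the ground-truth flight
#' start.
#'
#' @param config A [sim_config()].
#' @param body_mass Supported mass, kg.
#' @param jump_height Flight height implied by take-off velocity, m.
#' @param seed Integer seed for the force-plate noise.
#' @param t_quiet Quiet standing duration, s.
#' @param t_unweight Unweighting dip duration, s.
#' @param unweight_depth Peak downward acceleration of the dip, m/s^2.
#' @param t_push Propulsion half-period, s.
#' @return List with `grf` ([grf_recording()]) and `truth` (ground truth
#'   `unweight_end` and `flight_start` times, take-off velocity, and the
#'   analytic net impulse over the segmented window).
#' @export
simulate_cmj_grf <- function(config, body_mass = 74, jump_height = 0.25,
                             seed = config$seed, t_quiet = 1,
                             t_unweight = 0.35, unweight_depth = 1.26,
                             t_push = 0.30) {
  stopifnot(inherits(config, "sim_config"))
  if (body_mass <= 0 || jump_height <= 0)
    stop("`body_mass` and `jump_height` must be positive", call. = FALSE)
  g <- GRAVITY
  v_to <- sqrt(2 * g * jump_height)
  if (v_to > 5)
    warning("jump height implies a take-off velocity above 5 m/s", call. = FALSE)
  fs <- config$sampling_rate_grf

  # propulsion amplitude solving the impulse balance
  imp_needed <- v_to + unweight_depth * t_unweight / 2
  imp_fun <- function(C) C * t_push / pi * (1 + sqrt(1 - (g / C)^2)) - imp_needed
  C <- stats::uniroot(imp_fun, c(g + 1e-6, 400), tol = 1e-12)$root
  s_end <- t_push * (1 + asin(g / C) / pi)

  t_flight <- 2 * v_to / g
  t_tot <- t_quiet + t_unweight + s_end + t_flight * 0.8
  n <- floor(t_tot * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  vdot <- numeric(n)                     # centre-of-mass acceleration
  ph_u <- t >= t_quiet & t < t_quiet + t_unweight
  vdot[ph_u] <- -unweight_depth * sin(pi * (t[ph_u] - t_quiet) / t_unweight)^2
  t_p0 <- t_quiet + t_unweight
  ph_p <- t >= t_p0 & t < t_p0 + s_end
  vdot[ph_p] <- C * sin(pi * (t[ph_p] - t_p0) / t_push)
  ph_f <- t >= t_p0 + s_end
  vdot[ph_f] <- -g
  grfv <- body_mass * (g + vdot)
  grfv[ph_f] <- 0                        # exact free fall

  t_infl <- t_quiet + t_unweight / 4
  v_infl <- -unweight_depth * (t_unweight / 8 - t_unweight / (4 * pi))
  truth <- ground_truth(
    event_times = list(unweight_end = t_infl, flight_start = t_p0 + s_end),
    true_parameter_values = list(
      takeoff_velocity = v_to, jump_height = jump_height,
      net_impulse = body_mass * (v_to - v_infl),
      F_max = body_mass * C))

  local_seeded(seed, {
    if (config$noise_sd_grf > 0) {
      noise <- stats::rnorm(n, 0, config$noise_sd_grf)
      noise[ph_f] <- 0                   # plates read a clean zero in flight
      grfv <- pmax(0, grfv + noise)
    }
    list(grf = grf_recording(t, grfv, fs, body_mass), truth = truth)
  })
}

#' Simulate a cohort of trial-level parameter values
#'
#' Draws feature records directly at the parameter level with a prescribed
#' variance decomposition: each subject's limb-specific mean is drawn with
#' the between-subject SD and each trial around it with the within-subject
#' SD, so the true intraclass correlation is
#' \eqn{\sigma_b^2 / (\sigma_b^2 + \sigma_w^2)} by construction. Used to
#' verify ICC, SEM and MDC recovery.
#'
#' @param config A [sim_config()] whose `between_subject_sd` and
#'   `within_subject_sd` are named numeric vectors over parameters.
#' @param parameter_means Named numeric vector of cohort means; defaults to
#'   100 for every parameter named in the SD vectors.
#' @param task Task label stamped on the records.
#' @param limbs Limb labels to generate.
#' @return List with `records` (long data.frame: subject, limb, task, trial,
#'   parameter, value) and `truth` (per-parameter true ICC).
#' @export
simulate_cohort <- function(config, parameter_means = NULL, task = "SLS",
                            limbs = c("dominant", "non-dominant")) {
  stopifnot(inherits(config, "sim_config"))
  sb <- config$between_subject_sd; sw <- config$within_subject_sd
  if (is.null(sb) || is.null(sw) || is.null(names(sb)) || is.null(names(sw)))
    stop("config must carry named between/within subject SD vectors", call. = FALSE)
  pars <- names(sb)
  if (!setequal(pars, names(sw)))
    stop("between- and within-subject SDs must name the same parameters",
         call. = FALSE)
  sw <- sw[pars]
  if (any(sb == 0 & sw == 0) && config$n_subjects > 1)
    warning("degenerate variance: sigma_b = sigma_w = 0 for some parameter",
            call. = FALSE)
  if (is.null(parameter_means))
    parameter_means <- stats::setNames(rep(100, length(pars)), pars)
  true_icc <- ifelse(sb^2 + sw^2 > 0, sb^2 / (sb^2 + sw^2), NA_real_)
  names(true_icc) <- pars

  local_seeded(config$seed, {
    rows <- list()
    for (p in pars) {
      for (lb in limbs) {
        mu_s <- stats::rnorm(config$n_subjects, parameter_means[[p]], sb[[p]])
        vals <- stats::rnorm(config$n_subjects * config$n_trials,
                             rep(mu_s, each = config$n_trials), sw[[p]])
        rows[[length(rows) + 1L]] <- data.frame(
          subject = rep(seq_len(config$n_subjects), each = config$n_trials),
          limb = lb, task = task,
          trial = rep(seq_len(config$n_trials), config$n_subjects),
          parameter = p, value = vals, stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, rows)
    truth <- structure(list(event_times = list(),
                            true_parameter_values = as.list(parameter_means),
                            true_icc = true_icc), class = "ground_truth")
    list(records = records, truth = truth)
  })
}
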