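# Trial-level stability parameters.
#
# All RMS and peak parameters operate on the vector magnitude of the
# tri-axial signal (the reporting convention is one value per sensor, not
# per axis). Angular rates are computed internally in rad/s and reported in
# deg/s; accelerations stay in m/s^2.

RAD2DEG <- 180 / pi

as_window <- function(window, n) {
  w <- as.integer(window)
  if (!length(w)) stop("empty window", call. = FALSE)
  if (min(w) < 1L || max(w) > n) stop("window outside the signal", call. = FALSE)
  w
}

#' Root mean square of a tri-axial signal magnitude
#'
#' @param sig N x 3 matrix (or numeric vector, taken as a 1-D magnitude).
#' @param window Integer sample indices.
#' @return Scalar RMS of the vector norm over the window, input units.
#' @export
rms_norm <- function(sig, window) {
  sig <- as.matrix(sig)
  w <- as_window(window, nrow(sig))
  sqrt(mean(rowSums(sig[w, , drop = FALSE]^2)))
}

#' Peak of a tri-axial signal magnitude
#'
#' @inheritParams rms_norm
#' @return Scalar maximum of the vector norm over the window, input units.
#' @export
peak_norm <- function(sig, window) {
  sig <- as.matrix(sig)
  w <- as_window(window, nrow(sig))
  max(sqrt(rowSums(sig[w, , drop = FALSE]^2)))
}

#' Sway path of a planar trajectory
#'
#' Total length of the trajectory described by consecutive points in the
#' tibia transverse (y-z acceleration) plane.
#'
#' @param acc_yz N x 2 matrix of planar coordinates (m/s^2).
#' @return Scalar path length, input units.
#' @export
sway_path <- function(acc_yz) {
  acc_yz <- as.matrix(acc_yz)
  if (nrow(acc_yz) < 2) stop("at least 2 points are required", call. = FALSE)
  sum(sqrt(rowSums(diff(acc_yz)^2)))
}

#' Prediction ellipse of a planar point cloud
#'
#' Fits the ellipse expected to enclose a `coverage` fraction of the points,
#' from the eigen-decomposition of the sample covariance. The default
#' quantile is the small-sample F form `2 (N-1)/(N-2) F_coverage(2, N-2)`,
#' which converges to the chi-square quantile as N grows; the large-sample
#' chi-square form is available via `method`.
#'
#' @param points N x 2 matrix, N >= 3.
#' @param coverage Coverage fraction, default 0.90.
#' @param method `"f"` (small-sample, default) or `"chisq"`.
#' @return An `ellipse_fit` with semi-axes `a >= b`, `area = pi a b`,
#'   eccentricity `ecc = sqrt(1 - b^2/a^2)` and `center`.
#' @export
prediction_ellipse <- function(points, coverage = 0.90,
                               method = c("f", "chisq")) {
  method <- match.arg(method)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop("at least 3 points are required", call. = FALSE)
  S <- stats::cov(points)
  eg <- eigen(S, symmetric = TRUE)
  lam <- eg$values
  if (lam[1] <= 0 || lam[2] / lam[1] < 1e-12)
    stop("degenerate ellipse: rank-deficient covariance (eccentricity 1)",
         call. = FALSE)
  q <- switch(method,
    f = 2 * (n - 1) / (n - 2) * stats::qf(coverage, 2, n - 2),
    chisq = stats::qchisq(coverage, 2))
  a <- sqrt(q * lam[1]); b <- sqrt(q * lam[2])
  structure(list(a = a, b = b, area = pi * a * b,
                 ecc = sqrt(1 - b^2 / a^2),
                 center = colMeans(points), coverage = coverage,
                 quantile = q, axes = eg$vectors),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("<ellipse_fit> %.0f%% coverage: a = %.4g, b = %.4g, area = %.4g, ecc = %.4f\n",
              100 * x$coverage, x$a, x$b, x$area, x$ecc))
  invisible(x)
}

feature_record <- function(subject, limb, task, trial, values) {
  structure(list(subject = subject, limb = limb, task = task, trial = trial,
                 values = values), class = "feature_record")
}

#' @export
print.feature_record <- function(x, ...) {
  cat(sprintf("<feature_record> subject %s, %s limb, %s trial %s\n",
              x$subject, x$limb, x$task, x$trial))
  v <- unlist(x$values)
  print(signif(v[!is.na(v)], 4))
  invisible(x)
}

#' Collect feature records into a tidy table
#'
#' @param records List of `feature_record` objects.
#' @param wide If `TRUE`, return one row per trial with one column per
#'   parameter instead of the long layout.
#' @return Data.frame: long (subject, limb, task, trial, parameter, value)
#'   or wide (one parameter column per trial row).
#' @export
feature_table <- function(records, wide = FALSE) {
  if (inherits(records, "feature_record")) records <- list(records)
  long <- do.call(rbind, lapply(records, function(r) {
    data.frame(subject = r$subject, limb = r$limb, task = r$task,
               trial = r$trial, parameter = names(r$values),
               value = unlist(r$values, use.names = FALSE),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  if (!wide) return(long)
  w <- stats::reshape(long, idvar = c("subject", "limb", "task", "trial"),
                      timevar = "parameter", direction = "wide")
  names(w) <- sub("^value\\.", "", names(w))
  rownames(w) <- NULL
  w
}

#' Extract single-leg-squat parameters
#'
#' All parameters are computed on the eccentric phase
#' `[i_start, i_epe]`. RMS accelerations use the gravity-removed, vertically
#' aligned tibia acceleration (and the still-referenced foot acceleration,
#' the foot staying grounded during the squat); sway path, sway area and its
#' eccentricity come from the tibia body-frame y-z acceleration trajectory.
#'
#' @param tibia,foot Bias-corrected [imu_recording()]s.
#' @param orient The tibia `orientation_series`.
#' @param ev [task_events()] from [segment_sls()].
#' @param subject,limb,trial Metadata stamped on the record.
#' @param ellipse_coverage Coverage of the sway-area prediction ellipse.
#' @return A `feature_record`.
#' @export
extract_sls_features <- function(tibia, foot, orient, ev,
                                 subject = NA, limb = NA, trial = NA,
                                 ellipse_coverage = 0.90) {
  stopifnot(inherits(ev, "task_events"), ev$task == "SLS")
  if (is.null(tibia$acc) || is.null(foot$acc))
    stop("missing sensor stream: acc", call. = FALSE)
  fs <- tibia$fs
  w <- ev$i_start:ev$i_epe
  grav <- matrix(c(0, 0, GRAVITY), length(w), 3, byrow = TRUE)
  acc_leg <- orient$global_acc[w, , drop = FALSE] - grav
  foot_ref <- colMeans(foot$acc[seq_len(min(1000L, nrow(foot$acc))), , drop = FALSE])
  acc_foot <- sweep(foot$acc[w, , drop = FALSE], 2, foot_ref, "-")
  yz <- tibia$acc[w, c(2, 3), drop = FALSE]
  ell <- prediction_ellipse(yz, ellipse_coverage)
  values <- list(
    T_tot = (ev$i_epe - ev$i_start) / fs,
    RMSa_foot = rms_norm(acc_foot, seq_along(w)),
    RMSa_leg = rms_norm(acc_leg, seq_along(w)),
    RMSw_foot = rms_norm(foot$gyro, w) * RAD2DEG,
    RMSw_leg = rms_norm(tibia$gyro, w) * RAD2DEG,
    wpeak_foot = peak_norm(foot$gyro, w) * RAD2DEG,
    wpeak_leg = peak_norm(tibia$gyro, w) * RAD2DEG,
    SP = sway_path(yz),
    SA = ell$area,
    SAecc = ell$ecc)
  feature_record(subject, limb, "SLS", trial, values)
}

#' Extract crossover-hop parameters
#'
#' Temporal parameters follow the hop indexing `FT = LA_i - TO_{i-1}` and
#' `CT = TO_i - LA_{i-1}` applied to the second hop (the first and third
#' hops' take-off and landing technique being too variable for feature use);
#' all RMS/peak parameters are computed over the 100 ms risk window after
#' the second hop's landing, on the raw (bias-corrected, body-frame)
#' signals.
#'
#' @param foot,tibia Bias-corrected [imu_recording()]s.
#' @param orient Optional foot `orientation_series` (not needed by the
#'   magnitude-based parameters).
#' @param ev [task_events()] from [segment_cht()].
#' @param hop_distance Optional measured hop distance, m.
#' @param subject,limb,trial Metadata stamped on the record.
#' @return A `feature_record`.
#' @export
extract_cht_features <- function(foot, tibia, orient = NULL, ev,
                                 hop_distance = NULL,
                                 subject = NA, limb = NA, trial = NA) {
  stopifnot(inherits(ev, "task_events"), ev$task == "CHT")
  if (length(ev$la) < 2)
    stop("insufficient hops: at least 2 complete hops are required",
         call. = FALSE)
  fs <- foot$fs
  rw <- ev$risk_windows[[2]]
  w <- rw["start"]:rw["end"]
  values <- list(
    T_tot = (ev$la[length(ev$la)] - ev$to[1]) / fs,
    FT = (ev$la[2] - ev$to[2]) / fs,
    CT = if (length(ev$to) >= 3) (ev$to[3] - ev$la[2]) / fs else NA_real_,
    RMSa_foot = rms_norm(foot$acc, w),
    RMSa_leg = rms_norm(tibia$acc, w),
    RMSw_foot = rms_norm(foot$gyro, w) * RAD2DEG,
    RMSw_leg = rms_norm(tibia$gyro, w) * RAD2DEG,
    wpeak_foot = peak_norm(foot$gyro, w) * RAD2DEG,
    wpeak_leg = peak_norm(tibia$gyro, w) * RAD2DEG)
  if (!is.null(hop_distance)) values$hop_distance <- hop_distance
  feature_record(subject, limb, "CHT", trial, values)
}

#' Extract countermovement-jump parameters
#'
#' `F_max` is the maximum net vertical force over the segmented window
#' (unweighting end to flight start) and `AUC_F` the trapezoidal
#' time-integral of the net force over that window normalised by body mass
#' (m/s) -- the take-off velocity under the impulse-momentum theorem.
#'
#' @param grf A [grf_recording()].
#' @param seg The list returned by [segment_cmj()].
#' @param subject,limb,trial Metadata stamped on the record.
#' @return A `feature_record`.
#' @export
extract_cmj_features <- function(grf, seg, subject = NA, limb = NA, trial = NA) {
  stopifnot(inherits(seg$events, "task_events"), seg$events$task == "CMJ")
  net <- seg$net_force
  if (!length(net)) stop("empty segmented window", call. = FALSE)
  idx <- seg$events$i_unweight_end:(seg$events$i_flight_start - 1L)
  values <- list(
    F_max = max(net),
    AUC_F = pracma::trapz(grf$t[idx], net) / grf$body_mass)
  feature_record(subject, limb, "CMJ", trial, values)
}
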