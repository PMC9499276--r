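# CSV readers/writers, pipeline configuration and the end-to-end driver.

IMU_COLUMNS <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")

#' Write an IMU recording to CSV
#'
#' Columns `t, ax..az, gx..gz, mx..mz`, SI units, with a header row.
#'
#' @param rec An [imu_recording()].
#' @param path Output file path.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  d <- data.frame(rec$t, rec$acc, rec$gyro, rec$mag)
  names(d) <- IMU_COLUMNS
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Columns are matched by header name, so column order is free. Missing
#' columns, non-numeric cells and non-monotone time stamps are reported with
#' their location.
#'
#' @param path CSV file path.
#' @param location Sensor mounting site, `"tibia"` or `"foot"`.
#' @param fs Sampling rate; inferred from the time stamps when `NULL`.
#' @return An [imu_recording()].
#' @export
read_imu_csv <- function(path, location = c("tibia", "foot"), fs = NULL) {
  location <- match.arg(location)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(IMU_COLUMNS, names(d))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path, call. = FALSE)
  for (cl in IMU_COLUMNS) {
    if (!is.numeric(d[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(d[[cl]]))) & !is.na(d[[cl]]))
      stop(sprintf("parse error: non-numeric value in column '%s', row %d of %s",
                   cl, if (length(bad)) bad[1] else NA_integer_, path),
           call. = FALSE)
    }
  }
  bad_t <- which(diff(d$t) <= 0)
  if (length(bad_t))
    stop(sprintf("non-monotone time stamps at row(s) %s of %s",
                 paste(utils::head(bad_t + 1L, 5), collapse = ", "), path),
         call. = FALSE)
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$t))
  imu_recording(d$t, as.matrix(d[c("ax", "ay", "az")]),
                as.matrix(d[c("gx", "gy", "gz")]),
                as.matrix(d[c("mx", "my", "mz")]), fs, location)
}

#' Write / read a vertical-GRF recording as CSV
#'
#' Columns `t, grfv`; the body mass travels with the reader call (or a
#' ground-truth sidecar), not the CSV.
#'
#' @param rec A [grf_recording()].
#' @param path File path.
#' @export
write_grf_csv <- function(rec, path) {
  stopifnot(inherits(rec, "grf_recording"))
  utils::write.csv(data.frame(t = rec$t, grfv = rec$grfv), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_grf_csv
#' @param body_mass Supported body mass, kg.
#' @param fs Sampling rate; inferred from the time stamps when `NULL`.
#' @export
read_grf_csv <- function(path, body_mass, fs = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("t", "grfv"), names(d))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (is.null(fs)) fs <- 1 / stats::median(diff(d$t))
  grf_recording(d$t, d$grfv, fs, body_mass)
}

#' Write ground truth as a JSON sidecar
#'
#' @param truth A [ground_truth()].
#' @param path Output path.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every threshold and constant the pipeline applies, with defaults
#' matching the protocol this package implements. The configuration
#' serialises losslessly to JSON via [write_pipeline_config()].
#'
#' @param fs_imu,fs_grf Sampling rates, Hz.
#' @param k1,k2 Complementary-filter gains, 1/s.
#' @param sls_window Moving-SD window, samples.
#' @param sls_static_samples Static-reference window, samples.
#' @param sls_start_factor Start-rule threshold multiplier.
#' @param sls_sigma_scale Scaling of the moving SD in the start rule.
#' @param to_threshold Take-off threshold, rad/s^2.
#' @param la_threshold Landing jerk threshold, m/s^3.
#' @param t_risk Post-landing risk window, s.
#' @param ellipse_coverage Prediction-ellipse coverage fraction.
#' @param lsi_band Physiological LSI band, percent.
#' @param mdc_z z-value for the MDC.
#' @param flight_force_threshold CMJ flight-detection force threshold, N.
#' @param refractory Event refractory period, s.
#' @param cht_smooth_s,cmj_smooth_s Detector smoothing windows, s.
#' @param cmj_onset_band CMJ unweighting-onset band, N.
#' @param seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fs_imu = 500, fs_grf = 1000, k1 = 2.33, k2 = 7.44,
                            sls_window = 10, sls_static_samples = 1000,
                            sls_start_factor = 2, sls_sigma_scale = 10,
                            to_threshold = -0.6, la_threshold = 7,
                            t_risk = 0.100, ellipse_coverage = 0.90,
                            lsi_band = c(85, 115), mdc_z = 1.96,
                            flight_force_threshold = 5, refractory = 0.200,
                            cht_smooth_s = 0.08, cmj_smooth_s = 0.04,
                            cmj_onset_band = 20, seed = 1L) {
  cfg <- list(fs_imu = fs_imu, fs_grf = fs_grf, k1 = k1, k2 = k2,
              sls_window = as.integer(sls_window),
              sls_static_samples = as.integer(sls_static_samples),
              sls_start_factor = sls_start_factor,
              sls_sigma_scale = sls_sigma_scale,
              to_threshold = to_threshold, la_threshold = la_threshold,
              t_risk = t_risk, ellipse_coverage = ellipse_coverage,
              lsi_band = lsi_band, mdc_z = mdc_z,
              flight_force_threshold = flight_force_threshold,
              refractory = refractory, cht_smooth_s = cht_smooth_s,
              cmj_smooth_s = cmj_smooth_s, cmj_onset_band = cmj_onset_band,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(fs_imu > 0, fs_grf > 0, k1 >= 0, k2 >= 0, sls_window >= 2,
              sls_static_samples >= 100, sls_start_factor > 0,
              sls_sigma_scale > 0, to_threshold < 0, la_threshold > 0,
              t_risk > 0, ellipse_coverage > 0, ellipse_coverage < 1,
              length(lsi_band) == 2, lsi_band[1] < lsi_band[2], mdc_z > 0,
              flight_force_threshold >= 0, refractory >= 0,
              cht_smooth_s >= 0, cmj_smooth_s > 0, cmj_onset_band > 0)
  })
  structure(cfg, class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

process_imu_trial <- function(task, tibia, foot, config) {
  still <- seq_len(config$sls_static_samples)
  tibia <- remove_gyro_bias(tibia, still)
  foot <- remove_gyro_bias(foot, still)
  if (task == "SLS") {
    orient <- estimate_orientation(tibia, config$k1, config$k2)
    ev <- segment_sls(tibia_pitch(orient), tibia$fs,
                      static_samples = config$sls_static_samples,
                      window = config$sls_window,
                      start_factor = config$sls_start_factor,
                      sigma_scale = config$sls_sigma_scale)
    rec <- extract_sls_features(tibia, foot, orient, ev,
                                ellipse_coverage = config$ellipse_coverage)
  } else {
    ev <- segment_cht(foot, to_threshold = config$to_threshold,
                      la_threshold = config$la_threshold,
                      t_risk = config$t_risk, refractory = config$refractory,
                      smooth_s = config$cht_smooth_s)
    rec <- extract_cht_features(foot, tibia, NULL, ev)
  }
  list(features = rec, events = ev)
}

#' Run the full processing pipeline over a trial manifest
#'
#' Executes preprocessing, segmentation, feature extraction and cohort
#' reliability for every trial in the manifest. IMU tasks (`SLS`, `CHT`)
#' require `tibia_csv` and `foot_csv` paths; `CMJ` rows require `grf_csv`
#' and `body_mass`. Per-trial failures are recorded and skipped; the run
#' fails only if every trial fails.
#'
#' @param config A [pipeline_config()].
#' @param manifest Data.frame with columns `subject`, `limb`, `task`,
#'   `trial` plus the path columns above.
#' @param out_dir Optional output directory for the feature CSVs, events
#'   JSON, reliability JSON and run log.
#' @return List with `features` (long data.frame), `events`, `reliability`
#'   (a `cohort_summary`), `failures` and `log`.
#' @export
run_pipeline <- function(config, manifest, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(manifest) || !nrow(manifest))
    stop("empty input: the manifest contains no trials", call. = FALSE)
  records <- list(); events <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    tag <- sprintf("%s/%s/%s/trial%s", row$subject, row$limb, row$task, row$trial)
    res <- tryCatch({
      if (row$task %in% c("SLS", "CHT")) {
        tibia <- read_imu_csv(row$tibia_csv, "tibia", fs = config$fs_imu)
        foot <- read_imu_csv(row$foot_csv, "foot", fs = config$fs_imu)
        process_imu_trial(row$task, tibia, foot, config)
      } else if (row$task == "CMJ") {
        grf <- read_grf_csv(row$grf_csv, body_mass = row$body_mass,
                            fs = config$fs_grf)
        seg <- segment_cmj(grf, onset_band = config$cmj_onset_band,
                           flight_threshold = config$flight_force_threshold,
                           smooth_s = config$cmj_smooth_s)
        list(features = extract_cmj_features(grf, seg), events = seg$events)
      } else stop("unknown task: ", row$task)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[tag]] <- conditionMessage(res)
    } else {
      res$features$subject <- row$subject
      res$features$limb <- row$limb
      res$features$trial <- row$trial
      records[[tag]] <- res$features
      events[[tag]] <- res$events
    }
  }
  if (!length(records))
    stop("all trials failed: ",
         paste(names(failures), unlist(failures), sep = ": ", collapse = "; "),
         call. = FALSE)
  features <- feature_table(records)
  reliability <- tryCatch(
    summarize_cohort(features, mdc_z = config$mdc_z,
                     lsi_band = config$lsi_band),
    error = function(e) NULL)
  log_lines <- c(
    sprintf("kneestab pipeline run, %d/%d trial(s) processed",
            length(records), nrow(manifest)),
    "config:",
    vapply(names(unclass(config)), function(nm)
      sprintf("  %s = %s", nm, paste(config[[nm]], collapse = ", ")), ""),
    if (length(failures))
      c("failures:", sprintf("  %s: %s", names(failures), unlist(failures))))
  out <- list(features = features, events = events, reliability = reliability,
              failures = failures, log = log_lines)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(feature_table(records, wide = TRUE),
                     file.path(out_dir, "features_wide.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      lapply(events, function(e) jsonlite::fromJSON(task_events_json(e))),
      file.path(out_dir, "events.json"), auto_unbox = TRUE, digits = NA)
    if (!is.null(reliability)) {
      utils::write.csv(reliability$summary,
                       file.path(out_dir, "reliability.csv"), row.names = FALSE)
      jsonlite::write_json(
        lapply(unclass(reliability), function(d)
          if (is.data.frame(d)) d else NULL),
        file.path(out_dir, "reliability.json"), auto_unbox = TRUE, digits = NA)
    }
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}
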