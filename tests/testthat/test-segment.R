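fs <- 500

test_that("moving SD matches direct computation and handles edges", {
  expect_equal(moving_sd(rep(3.7, 50), 10), rep(0, 50))
  x <- c(rep(0, 20), rep(1, 20))
  ms <- moving_sd(x, 10)
  # window with five 0s and five 1s
  expect_equal(max(ms), sd(c(rep(0, 5), rep(1, 5))))
  expect_equal(ms[25], sd(c(rep(0, 5), rep(1, 5))))
  # degenerate window: one global SD replicated
  y <- rnorm(30)
  expect_equal(moving_sd(y, 30), rep(sd(y), 30))
  expect_error(moving_sd(y, 31), "exceeds")
  expect_error(moving_sd(y, 1), "at least 2")
})

test_that("noiseless squat events are recovered within one sample", {
  s <- simulate_sls(clean_config(), seed = 1, sway_scale = 0)
  o <- estimate_orientation(remove_gyro_bias(s$tibia))
  ev <- segment_sls(tibia_pitch(o), fs)
  tt <- truth_idx(s$truth, fs)
  expect_lte(abs(ev$i_start - tt["sls_start"]), 1)
  expect_lte(abs(ev$i_epe - tt["epe"]), 1)
  expect_lte(abs(ev$i_end - tt["sls_end"]), 1.5)  # truth falls between samples
})

test_that("squat events stay within 10 ms of truth under sensor noise", {
  cfg <- sim_config()
  errs <- sapply(1:25, function(seed) {
    s <- simulate_sls(cfg, seed = seed)
    o <- estimate_orientation(remove_gyro_bias(s$tibia))
    ev <- segment_sls(tibia_pitch(o), fs)
    tt <- truth_idx(s$truth, fs)
    c(ev$i_start, ev$i_epe, ev$i_end) - tt
  })
  expect_true(all(abs(errs) <= 0.010 * fs))
})

test_that("a flat pitch signal raises a no-movement error", {
  expect_error(segment_sls(rep(0, 3000), fs), "no movement")
  expect_error(segment_sls(rep(12.5, 3000), fs), "no movement")
})

test_that("an unterminated squat warns and reports the last sample", {
  s <- simulate_sls(clean_config(), seed = 1, sway_scale = 0)
  o <- estimate_orientation(remove_gyro_bias(s$tibia))
  p <- tibia_pitch(o)
  i_epe <- which.max(p)
  p_trunc <- p[1:(i_epe + 50)]            # cut before the return completes
  expect_warning(ev <- segment_sls(p_trunc, fs), "unterminated")
  expect_equal(ev$i_end, length(p_trunc))
})

test_that("noiseless triple hop take-offs and landings are exact to one sample", {
  h <- simulate_cht(clean_config(), seed = 1)
  ev <- segment_cht(remove_gyro_bias(h$foot))
  tt <- truth_idx(h$truth, fs)
  expect_length(ev$to, 3)
  expect_length(ev$la, 3)
  expect_true(all(abs(ev$to - tt[c("to1", "to2", "to3")]) <= 1.01))
  expect_true(all(abs(ev$la - tt[c("la1", "la2", "la3")]) <= 1.01))
  # risk windows: 100 ms, starting at each landing
  expect_true(all(vapply(ev$risk_windows,
                         function(w) w["end"] - w["start"] + 1, 0) ==
                    round(0.1 * fs)))
})

test_that("hop events stay within 10 ms of truth under the stated noise", {
  cfg <- sim_config(noise_sd_acc = 0.2)
  hits <- sapply(1:25, function(seed) {
    h <- simulate_cht(cfg, seed = seed)
    ev <- segment_cht(remove_gyro_bias(h$foot))
    tt <- truth_idx(h$truth, fs)
    length(ev$to) == 3 &&
      all(abs(c(ev$to, ev$la) - tt[c(1, 3, 5, 2, 4, 6)]) <= 0.010 * fs)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("a landing jerk below the threshold leaves events unbalanced", {
  h <- simulate_cht(clean_config(), seed = 1)
  foot <- remove_gyro_bias(h$foot)
  expect_error(segment_cht(foot, la_threshold = 5000), "unbalanced")
  # and the error names the detected take-offs
  err <- tryCatch(segment_cht(foot, la_threshold = 5000),
                  error = function(e) conditionMessage(e))
  expect_match(err, "take-off")
})

test_that("raising the landing threshold never adds landings", {
  h <- simulate_cht(sim_config(), seed = 3)
  foot <- remove_gyro_bias(h$foot)
  counts <- vapply(c(5, 50, 500, 1500), function(thr) {
    tryCatch(length(segment_cht(foot, la_threshold = thr)$la),
             error = function(e) 0L)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("event times agree across sampling rates", {
  ev500 <- segment_cht(remove_gyro_bias(
    simulate_cht(clean_config(), seed = 4)$foot))
  ev1k <- segment_cht(remove_gyro_bias(
    simulate_cht(clean_config(sampling_rate_imu = 1000), seed = 4)$foot))
  expect_true(all(abs((ev500$to - 1) / 500 - (ev1k$to - 1) / 1000) <= 1 / 500))
  expect_true(all(abs((ev500$la - 1) / 500 - (ev1k$la - 1) / 1000) <= 1 / 500))
})

test_that("CMJ events land within 10 ms of truth and the impulse checks out", {
  cfg <- sim_config()
  for (seed in 1:10) {
    j <- simulate_cmj_grf(cfg, body_mass = 74, jump_height = 0.25, seed = seed)
    seg <- segment_cmj(j$grf)
    tt <- truth_idx(j$truth, j$grf$fs)
    expect_lte(abs(seg$events$i_unweight_end - tt["unweight_end"]),
               0.010 * j$grf$fs)
    expect_lte(abs(seg$events$i_flight_start - tt["flight_start"]),
               0.010 * j$grf$fs)
  }
  # takeoff velocity from the segmented net impulse
  j <- simulate_cmj_grf(clean_config(), body_mass = 74, jump_height = 0.25,
                        seed = 1)
  seg <- segment_cmj(j$grf)
  auc <- extract_cmj_features(j$grf, seg)$values$AUC_F
  expect_lt(abs(auc / sqrt(2 * 9.80665 * 0.25) - 1), 0.02)
})

test_that("constant GRF at body weight raises a no-flight error", {
  n <- 3000
  rec <- grf_recording((0:(n - 1)) / 1000, rep(74 * 9.80665, n), 1000, 74)
  expect_error(segment_cmj(rec), "no flight")
})

test_that("detected indices always lie inside the recording", {
  for (seed in 1:5) {
    h <- simulate_cht(sim_config(), seed = seed)
    ev <- segment_cht(remove_gyro_bias(h$foot))
    n <- length(h$foot$t)
    expect_true(all(c(ev$to, ev$la) >= 1 & c(ev$to, ev$la) <= n))
    expect_true(all(vapply(ev$risk_windows, function(w) w["end"], 0) <= n))
  }
})
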