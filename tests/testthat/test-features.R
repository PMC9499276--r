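fs <- 500

test_that("rms_norm and peak_norm follow hand-computed values", {
  const <- matrix(c(1, 2, 2), 5, 3, byrow = TRUE)    # norm 3 everywhere
  expect_equal(rms_norm(const, 1:5), 3)
  expect_equal(peak_norm(const, 1:5), 3)
  expect_equal(rms_norm(matrix(0, 4, 3), 1:4), 0)
  two <- rbind(c(3, 0, 0), c(0, 4, 0))               # norms 3 and 4
  expect_equal(rms_norm(two, 1:2), sqrt((9 + 16) / 2))
  expect_equal(rms_norm(two, 1:2), 3.5355339, tolerance = 1e-7)
  imp <- matrix(0, 10, 3); imp[6, 1] <- 10
  expect_equal(peak_norm(imp, 1:10), 10)
  expect_error(rms_norm(two, integer(0)), "empty")
  expect_error(peak_norm(two, integer(0)), "empty")
})

test_that("sway path is the polygon length of the planar trajectory", {
  expect_equal(sway_path(rbind(c(1, 1), c(1, 1), c(1, 1))), 0)
  expect_equal(sway_path(rbind(c(0, 0), c(3, 4))), 5)
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  expect_equal(sway_path(square), 4)
  expect_error(sway_path(rbind(c(0, 0))), "2 points")
})

test_that("prediction ellipse covers the nominal fraction and has exact shape", {
  withr::with_seed(100, {
    pts <- matrix(rnorm(2e5), ncol = 2)
    e <- prediction_ellipse(pts, 0.90)
    inside <- mahalanobis(pts, e$center, cov(pts)) <= e$quantile
    expect_lt(abs(mean(inside) - 0.90), 0.01)
    # eigenvalue splitting of a sample covariance is O(sqrt(2/n)), so the
    # fitted eccentricity of an isotropic cloud at n = 1e5 sits near 0.1
    expect_lt(e$ecc, 0.15)
  })
  # constructed covariance with axis ratio 2:1
  pts4 <- rbind(c(2, 0), c(-2, 0), c(0, 1), c(0, -1))
  e4 <- prediction_ellipse(pts4)
  expect_equal(e4$a / e4$b, 2)
  expect_equal(e4$ecc, sqrt(1 - 1 / 4))
  expect_equal(e4$ecc, 0.8660254, tolerance = 1e-7)
  expect_equal(e4$area, pi * e4$a * e4$b)
  # collinear points are degenerate
  line <- cbind(1:10, 2 * (1:10))
  expect_error(prediction_ellipse(line), "degenerate")
  # the F quantile converges to the chi-square quantile
  big <- matrix(rnorm(2e4), ncol = 2)
  qf_ <- prediction_ellipse(big, method = "f")$quantile
  expect_equal(qf_, qchisq(0.9, 2), tolerance = 1e-3)
})

test_that("squat features honour the eccentric-phase window", {
  s <- simulate_sls(clean_config(), seed = 1)   # sway on, sensors noiseless
  tib <- remove_gyro_bias(s$tibia); ft <- remove_gyro_bias(s$foot)
  o <- estimate_orientation(tib)
  ev <- segment_sls(tibia_pitch(o), fs)
  r <- extract_sls_features(tib, ft, o, ev)
  expect_equal(r$values$T_tot, s$truth$true_parameter_values$T_tot,
               tolerance = 6 / fs)
  # purity: same input, same output
  expect_identical(unlist(r$values),
                   unlist(extract_sls_features(tib, ft, o, ev)$values))
  # RMS never exceeds the peak
  expect_lte(r$values$RMSw_leg, r$values$wpeak_leg)
  expect_lte(r$values$RMSw_foot, r$values$wpeak_foot)
})

test_that("sway area matches the analytic ellipse for constructed input", {
  # replace the windowed tibia y-z trace by a known Gaussian cloud
  withr::with_seed(5, {
    s <- simulate_sls(clean_config(), seed = 1)
    tib <- remove_gyro_bias(s$tibia); ft <- remove_gyro_bias(s$foot)
    o <- estimate_orientation(tib)
    ev <- segment_sls(tibia_pitch(o), fs)
    n <- length(tib$t)
    tib$acc[, 2] <- rnorm(n, 0, 2)
    tib$acc[, 3] <- rnorm(n, 0, 1)
    r <- extract_sls_features(tib, ft, o, ev)
    w <- ev$i_start:ev$i_epe
    q <- 2 * (length(w) - 1) / (length(w) - 2) * qf(0.9, 2, length(w) - 2)
    analytic <- pi * q * 2 * 1                     # pi * q * sigma1 * sigma2
    expect_lt(abs(r$values$SA / analytic - 1), 0.15)  # sampling variation
  })
})

test_that("hop features follow the second-hop rule and configured durations", {
  h <- simulate_cht(clean_config(), seed = 2,
                    hop_params = list(flight_s = c(0.25, 0.30, 0.35),
                                      contact_s = c(0.45, 0.40)))
  foot <- remove_gyro_bias(h$foot); tib <- remove_gyro_bias(h$tibia)
  ev <- segment_cht(foot)
  r <- extract_cht_features(foot, tib, NULL, ev, hop_distance = 4.9)
  expect_equal(r$values$FT, 0.30, tolerance = 1.5 / fs)
  expect_equal(r$values$CT, 0.40, tolerance = 2 / fs)
  expect_equal(r$values$T_tot, h$truth$true_parameter_values$T_tot,
               tolerance = 2 / fs)
  expect_equal(r$values$hop_distance, 4.9)
  # doubling the configured contact doubles the detected contact
  h2 <- simulate_cht(clean_config(), seed = 2,
                     hop_params = list(flight_s = c(0.25, 0.30, 0.35),
                                       contact_s = c(0.45, 0.80)))
  r2 <- extract_cht_features(foot, tib, NULL,
                             segment_cht(remove_gyro_bias(h2$foot)))
  expect_equal(r2$values$CT, 0.80, tolerance = 2 / fs)
  # risk-window peak matches the generator's stored clean peak
  expect_equal(r$values$wpeak_foot, h$truth$true_parameter_values$wpeak_foot,
               tolerance = 0.01 * r$values$wpeak_foot)
})

test_that("fewer than two hops is an error", {
  h <- simulate_cht(clean_config(), seed = 2)
  foot <- remove_gyro_bias(h$foot); tib <- remove_gyro_bias(h$tibia)
  ev <- segment_cht(foot)
  ev1 <- task_events("CHT", fs, to = ev$to[1], la = ev$la[1],
                     risk_windows = ev$risk_windows[1])
  expect_error(extract_cht_features(foot, tib, NULL, ev1), "insufficient hops")
})

test_that("a constant angular-velocity risk window gives RMS equal to peak", {
  h <- simulate_cht(clean_config(), seed = 2)
  foot <- remove_gyro_bias(h$foot); tib <- remove_gyro_bias(h$tibia)
  ev <- segment_cht(foot)
  w <- ev$risk_windows[[2]]
  foot$gyro[w["start"]:w["end"], ] <-
    matrix(c(2, 2, 1), w["end"] - w["start"] + 1, 3, byrow = TRUE)  # norm 3
  r <- extract_cht_features(foot, tib, NULL, ev)
  expect_equal(r$values$RMSw_foot, 3 * 180 / pi)
  expect_equal(r$values$wpeak_foot, 3 * 180 / pi)
})

test_that("CMJ features follow rectangle and triangle oracles", {
  # constant net force F over duration T: AUC_F = F T / m
  n <- 2001; fsg <- 1000; m <- 80
  bw <- m * 9.80665
  grfv <- rep(bw, n)
  grfv[1001:1500] <- bw + 200                        # 0.5 s of +200 N
  grfv[1501:n] <- 0
  rec <- grf_recording((0:(n - 1)) / fsg, grfv, fsg, m)
  seg <- list(events = task_events("CMJ", fsg, i_unweight_end = 1001L,
                                   i_flight_start = 1501L),
              net_force = grfv[1001:1500] - bw, body_weight = bw)
  r <- extract_cmj_features(rec, seg)
  expect_equal(r$values$F_max, 200)
  expect_equal(r$values$AUC_F, 200 * 0.499 / m, tolerance = 1e-9)
  # triangular pulse peaking at 800 N
  tri <- c(seq(0, 800, length.out = 250), seq(800, 0, length.out = 250))
  seg2 <- list(events = task_events("CMJ", fsg, i_unweight_end = 1001L,
                                    i_flight_start = 1501L),
               net_force = tri, body_weight = bw)
  expect_equal(extract_cmj_features(rec, seg2)$values$F_max, 800)
})

test_that("features are scale-equivariant and SAecc rotation-invariant", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      sig <- matrix(rnorm(300), ncol = 3)
      w <- 1:100
      c_ <- runif(1, 0.5, 3)
      expect_equal(rms_norm(sig * c_, w), c_ * rms_norm(sig, w))
      expect_equal(peak_norm(sig * c_, w), c_ * peak_norm(sig, w))
      expect_gte(peak_norm(sig, w), rms_norm(sig, w))
      yz <- sig[, 1:2]
      expect_equal(sway_path(yz * c_), c_ * sway_path(yz))
      e1 <- prediction_ellipse(yz); e2 <- prediction_ellipse(yz * c_)
      expect_equal(e2$area, c_^2 * e1$area)
      expect_equal(e2$ecc, e1$ecc)
      # rotation within the plane leaves the eccentricity unchanged
      ang <- runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
      e3 <- prediction_ellipse(yz %*% rot)
      expect_equal(e3$ecc, e1$ecc, tolerance = 1e-9)
      expect_equal(e3$area, e1$area, tolerance = 1e-9)
    }
  })
})

test_that("degree reporting is an exact rad-to-deg round trip", {
  s <- simulate_cht(sim_config(), seed = 5)
  foot <- remove_gyro_bias(s$foot); tib <- remove_gyro_bias(s$tibia)
  ev <- segment_cht(foot)
  r <- extract_cht_features(foot, tib, NULL, ev)
  w <- ev$risk_windows[[2]]["start"]:ev$risk_windows[[2]]["end"]
  expect_equal(r$values$RMSw_foot, rms_norm(foot$gyro, w) * 180 / pi)
})
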