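test_that("ICC matches a from-first-principles ANOVA oracle", {
  m <- matrix(c(9, 2, 5,
                6, 1, 7,
                8, 4, 6,
                7, 1, 2), 4, 3, byrow = TRUE)
  r <- icc_absolute_agreement(m)
  # independent oracle: mean squares from stats::aov
  d <- data.frame(y = as.vector(m), s = factor(rep(1:4, 3)),
                  tr = factor(rep(1:3, each = 4)))
  a <- summary(stats::aov(y ~ s + tr, data = d))[[1]]
  msr <- a["s", "Mean Sq"]; msc <- a["tr", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  icc_oracle <- (msr - mse) / (msr + 2 * mse + (3 / 4) * (msc - mse))
  expect_equal(r$icc, icc_oracle, tolerance = 1e-12)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  # identical columns across varying rows: perfect agreement
  perfect <- matrix(rep(c(3, 7, 1, 9), 3), 4, 3)
  expect_equal(icc_absolute_agreement(perfect)$icc, 1)
  expect_error(icc_absolute_agreement(matrix(5, 4, 3)), "zero total variance")
  expect_error(icc_absolute_agreement(m[1, , drop = FALSE]), "at least 2")
})

test_that("ICC is invariant under shift and positive scaling", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      m <- matrix(rnorm(30, 10, 2), 10, 3)
      r0 <- icc_absolute_agreement(m)$icc
      expect_equal(icc_absolute_agreement(m + 7.3)$icc, r0, tolerance = 1e-12)
      expect_equal(icc_absolute_agreement(m * 2.6)$icc, r0, tolerance = 1e-12)
    }
  })
})

test_that("confidence intervals cover the true ICC at the nominal rate", {
  withr::with_seed(31, {
    sb <- sqrt(0.7); sw <- sqrt(0.3)          # true ICC 0.7
    hits <- replicate(600, {
      m <- matrix(rnorm(17 * 3, rep(rnorm(17, 0, sb), 3), sw), 17, 3)
      r <- icc_absolute_agreement(m)
      r$ci_low <= 0.7 && 0.7 <= r$ci_high
    })
    expect_gte(mean(hits), 0.92)
    expect_lte(mean(hits), 0.98)
  })
})

test_that("SEM and MDC follow their closed forms", {
  r <- sem_mdc(10, 0.75)
  expect_equal(r$sem, 5)
  expect_equal(r$mdc, 5 * 1.96 * sqrt(2))
  expect_equal(r$mdc, 13.859, tolerance = 1e-4)
  expect_equal(sem_mdc(10, 1)$mdc, 0)
  expect_equal(sem_mdc(0, 0.3)$sem, 0)
  expect_error(sem_mdc(-1, 0.5), "non-negative")
  expect_error(sem_mdc(1, 1.2), "0, 1")
  # monotonicity: MDC decreases in ICC, increases in SD
  iccs <- seq(0, 1, 0.1)
  expect_true(all(diff(sapply(iccs, function(i) sem_mdc(4, i)$mdc)) <= 0))
  sds <- seq(0.5, 5, 0.5)
  expect_true(all(diff(sapply(sds, function(s) sem_mdc(s, 0.6)$mdc)) >= 0))
})

test_that("LSI reproduces the published worked examples", {
  expect_equal(lsi(1, 1)$lsi, 100)
  expect_true(lsi(1, 1)$physiological)
  # crossover-hop distances
  r1 <- lsi(4.91, 4.94)
  expect_equal(round(r1$lsi), 99)
  expect_true(r1$physiological)
  # CMJ maximal force group means
  r2 <- lsi(482.0, 520.6)
  expect_equal(round(r2$lsi), 93)
  expect_true(r2$physiological)
  expect_error(lsi(3, 0), "undefined LSI")
})

test_that("LSI reciprocity holds: lsi(a,b) * lsi(b,a) = 10000", {
  withr::with_seed(41, {
    a <- runif(20, 0.1, 50); b <- runif(20, 0.1, 50)
    expect_equal(lsi(a, b)$lsi * lsi(b, a)$lsi, rep(1e4, 20))
  })
})

test_that("reliability sample size reproduces the planning example", {
  expect_identical(sample_size_reliability(0.3, 0.7, 0.05, 0.8, k = 3), 16L)
  # widening the reliability gap shrinks the sample
  expect_lt(sample_size_reliability(0.3, 0.9, 0.05, 0.8, k = 3),
            sample_size_reliability(0.3, 0.7, 0.05, 0.8, k = 3))
  # more repetitions per subject need fewer subjects
  expect_gt(sample_size_reliability(0.3, 0.7, k = 2),
            sample_size_reliability(0.3, 0.7, k = 3))
  expect_error(sample_size_reliability(0.7, 0.3), "rho0 < rho1")
})

test_that("cohort ICC recovery converges to the variance-ratio truth", {
  # sigma_b = sigma_w: true ICC 0.5; large cohort, replicate mean
  est <- sapply(1:100, function(r) {
    cfg <- sim_config(n_subjects = 200, n_trials = 3, seed = 1000 + r,
                      between_subject_sd = c(P = 1),
                      within_subject_sd = c(P = 1))
    co <- simulate_cohort(cfg, parameter_means = c(P = 10), limbs = "dominant")
    icc_absolute_agreement(trial_matrix(co$records, "P"))$icc
  })
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("cohort summary aggregates medians, reliability and symmetry", {
  cfg <- sim_config(n_subjects = 12, n_trials = 3, seed = 77,
                    between_subject_sd = c(RMSa_foot = 5, wpeak_leg = 30),
                    within_subject_sd = c(RMSa_foot = 2, wpeak_leg = 10))
  co <- simulate_cohort(cfg, parameter_means = c(RMSa_foot = 80,
                                                 wpeak_leg = 800),
                        task = "CHT")
  s <- summarize_cohort(co$records)
  expect_setequal(unique(s$summary$parameter), c("RMSa_foot", "wpeak_leg"))
  expect_true(all(is.finite(s$summary$icc)))
  expect_true(all(s$summary$mdc >= 0))
  expect_true(!is.null(s$lsi) && all(abs(s$lsi$mean - 100) < 20))
  # group averages: the acceleration family contains only RMSa_foot here
  acc_rows <- s$summary$parameter == "RMSa_foot"
  gi <- s$group_icc[s$group_icc$group == "acceleration", ]
  expect_equal(gi$icc, mean(s$summary$icc[acc_rows]))
})

test_that("single trial per subject: the median equals that trial", {
  rec <- data.frame(subject = 1:4, limb = "dominant", task = "SLS",
                    trial = 1, parameter = "T_tot", value = c(2, 3, 4, 5))
  med <- aggregate(value ~ subject, rec, kneestab:::lower_median)
  expect_equal(med$value, c(2, 3, 4, 5))
  # lower median for even counts
  expect_equal(kneestab:::lower_median(c(1, 2, 3, 4)), 2)
  expect_equal(kneestab:::lower_median(c(3, 1)), 1)
})

test_that("group-average ICC matches direct averaging of published cells", {
  tab4 <- data.frame(
    parameter = rep(c("RMSa_foot", "RMSa_leg", "RMSw_foot", "RMSw_leg",
                      "wpeak_foot", "wpeak_leg"), each = 2),
    limb = rep(c("dominant", "non-dominant"), 6),
    icc = c(0.45, 0.42, 0.72, 0.25,
            0.63, 0.66, 0.63, 0.50, 0.70, 0.65, 0.60, 0.66))
  expect_equal(average_icc(tab4, c("RMSa_foot", "RMSa_leg")), 0.46)
  expect_equal(round(average_icc(tab4, c("RMSw_foot", "RMSw_leg",
                                         "wpeak_foot", "wpeak_leg")), 2),
               0.63)
  expect_error(average_icc(tab4, "nope"), "no matching")
})
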