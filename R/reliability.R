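# Test-retest reliability statistics: absolute-agreement two-way ICC with
# confidence intervals, SEM / minimum detectable change, limb symmetry
# index, reliability-study sample-size planning and cohort summaries.

#' Reshape trial-level records into a subjects x trials matrix
#'
#' @param records Long data.frame with columns subject, limb, task, trial,
#'   parameter, value.
#' @param parameter,limb,task Condition selecting one matrix.
#' @return Numeric matrix, one row per subject, one column per trial.
#' @export
trial_matrix <- function(records, parameter, limb = NULL, task = NULL) {
  d <- records[records$parameter == parameter, ]
  if (!is.null(limb)) d <- d[d$limb == limb, ]
  if (!is.null(task)) d <- d[d$task == task, ]
  if (!nrow(d)) stop("no records match the requested condition", call. = FALSE)
  subj <- sort(unique(d$subject))
  trials <- sort(unique(d$trial))
  m <- matrix(NA_real_, length(subj), length(trials),
              dimnames = list(subj, trials))
  m[cbind(match(d$subject, subj), match(d$trial, trials))] <- d$value
  drop_rows <- apply(m, 1, anyNA)
  if (any(drop_rows)) {
    message(sum(drop_rows), " subject(s) excluded listwise for missing trials")
    m <- m[!drop_rows, , drop = FALSE]
  }
  m
}

#' Absolute-agreement intraclass correlation (two-way model)
#'
#' Single-measurement absolute-agreement ICC from the two-way
#' subjects-by-trials ANOVA decomposition,
#' \deqn{ICC = (MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n)(MS_C - MS_E)),}
#' with the 95% confidence interval and p-value from the McGraw-Wong
#' F-distribution formulas. The average-measurement form is available via
#' `type = "average"`.
#'
#' @param m Subjects x trials numeric matrix (n >= 2 rows, k >= 2 columns,
#'   no missing cells).
#' @param alpha Two-sided confidence level is `1 - alpha`.
#' @param type `"single"` (default) or `"average"`.
#' @param mdc_z z-value for the minimum detectable change (95% by default).
#' @return A `reliability_result`: `icc`, `ci_low`, `ci_high`, `p`, `sem`,
#'   `mdc`, `mean`, `sd` (over all trial values), `n`, `k`.
#' @export
icc_absolute_agreement <- function(m, alpha = 0.05,
                                   type = c("single", "average"),
                                   mdc_z = 1.96) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells: exclude incomplete subjects first",
                     call. = FALSE)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 trials", call. = FALSE)
  if (stats::var(as.vector(m)) == 0)
    stop("undefined ICC: zero total variance", call. = FALSE)

  mu <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  msr <- k * sum((rm_ - mu)^2) / (n - 1)
  msc <- n * sum((cm_ - mu)^2) / (k - 1)
  mse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + mu)^2) /
    ((n - 1) * (k - 1))

  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # McGraw-Wong CI for the single-measurement absolute-agreement form
  a <- (k * icc1) / (n * (1 - icc1))
  b <- 1 + (k * icc1 * (n - 1)) / (n * (1 - icc1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- stats::qf(1 - alpha / 2, n - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  sb <- function(r) ifelse(r >= 1, 1, k * r / (1 + (k - 1) * r))  # Spearman-Brown
  if (type == "average") {
    icc_out <- (msr - mse) / (msr + (msc - mse) / n)
    lo <- sb(lo); hi <- sb(hi)
  } else {
    icc_out <- icc1
  }
  sd_all <- stats::sd(as.vector(m))
  sm <- sem_mdc(sd_all, max(0, min(1, icc_out)), z = mdc_z)
  structure(list(icc = icc_out, ci_low = lo, ci_high = hi, p = p,
                 sem = sm$sem, mdc = sm$mdc,
                 mean = mu, sd = sd_all, n = n, k = k, type = type,
                 ms = c(msr = msr, msc = msc, mse = mse)),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> ICC(%s) = %.3f [%.3f, %.3f], p = %.3g\n",
              x$type, x$icc, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  mean %.4g, SD %.4g, SEM %.4g, MDC %.4g (n = %d, k = %d)\n",
              x$mean, x$sd, x$sem, x$mdc, x$n, x$k))
  invisible(x)
}

#' Standard error of measurement and minimum detectable change
#'
#' `SEM = SD * sqrt(1 - ICC)`; `MDC = SEM * z * sqrt(2)` (z = 1.96 for a 95%
#' confidence level).
#'
#' @param sd Standard deviation of the measurements, parameter units.
#' @param icc Intraclass correlation in `[0, 1]`.
#' @param z z-value of the confidence level.
#' @return List with `sem` and `mdc`.
#' @export
sem_mdc <- function(sd, icc, z = 1.96) {
  if (any(sd < 0)) stop("`sd` must be non-negative", call. = FALSE)
  if (any(icc < 0 | icc > 1)) stop("`icc` must lie in [0, 1]", call. = FALSE)
  sem <- sd * sqrt(1 - icc)
  list(sem = sem, mdc = sem * z * sqrt(2))
}

#' Limb symmetry index
#'
#' `LSI = non-dominant / dominant * 100`; values inside the physiological
#' band (85-115% by default) indicate between-limb symmetry.
#'
#' @param nondom,dom Parameter values for the non-dominant and dominant limb.
#' @param band Physiological band, percent.
#' @return List with `lsi` (percent) and `physiological` (logical);
#'   vectorised over the inputs.
#' @export
lsi <- function(nondom, dom, band = c(85, 115)) {
  if (any(dom == 0)) stop("undefined LSI: dominant-limb value is zero",
                          call. = FALSE)
  v <- nondom / dom * 100
  structure(list(lsi = v, physiological = v >= band[1] & v <= band[2],
                 band = band), class = "lsi_result")
}

#' @export
print.lsi_result <- function(x, ...) {
  cat(sprintf("<lsi_result> LSI = %s%% (physiological band %g-%g%%)\n",
              paste(sprintf("%.1f", x$lsi), collapse = ", "),
              x$band[1], x$band[2]))
  invisible(x)
}

#' Sample size for an ICC reliability study
#'
#' Walter-Eliasziw-Donner approximation for the number of subjects needed to
#' distinguish an expected reliability `rho1` from a minimum acceptable
#' reliability `rho0` with `k` repetitions:
#' \deqn{n = 1 + \frac{2k(z_{\alpha/2}+z_\beta)^2}{(k-1)(\ln C_0)^2},\quad
#'       C_0 = \frac{1 + k\rho_0/(1-\rho_0)}{1 + k\rho_1/(1-\rho_1)}.}
#'
#' @param rho0 Minimum acceptable reliability, `0 <= rho0 < rho1`.
#' @param rho1 Expected reliability, `< 1`.
#' @param alpha Significance level (two-sided by default).
#' @param power Target power.
#' @param k Number of repetitions per subject.
#' @param two_sided Use `alpha/2` (default) or one-sided `alpha`.
#' @param rounding `"nearest"` (default) or `"ceiling"`.
#' @return Integer number of subjects.
#' @export
sample_size_reliability <- function(rho0 = 0.3, rho1 = 0.7, alpha = 0.05,
                                    power = 0.8, k = 3, two_sided = TRUE,
                                    rounding = c("nearest", "ceiling")) {
  rounding <- match.arg(rounding)
  if (!(rho0 >= 0 && rho0 < rho1 && rho1 < 1))
    stop("need 0 <= rho0 < rho1 < 1", call. = FALSE)
  if (k < 2) stop("`k` must be at least 2", call. = FALSE)
  za <- stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
  zb <- stats::qnorm(power)
  c0 <- (1 + k * rho0 / (1 - rho0)) / (1 + k * rho1 / (1 - rho1))
  n <- 1 + 2 * k * (za + zb)^2 / ((k - 1) * log(c0)^2)
  as.integer(if (rounding == "nearest") round(n) else ceiling(n))
}

# lower median: for even counts take the lower of the two central values
lower_median <- function(x) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) return(NA_real_)
  x[floor((length(x) + 1) / 2)]
}

#' Average ICC over a named parameter group
#'
#' @param summary_df Data.frame with columns `parameter`, `icc` (and
#'   optionally `limb`, averaged over).
#' @param parameters Character vector naming the group members.
#' @return Mean ICC over the matching rows.
#' @export
average_icc <- function(summary_df, parameters) {
  rows <- summary_df$parameter %in% parameters
  if (!any(rows)) stop("no matching parameters", call. = FALSE)
  mean(summary_df$icc[rows])
}

#' Cohort-level summary: medians, reliability and limb symmetry
#'
#' For every task, limb and parameter: the per-subject median over trials
#' (lower median for even trial counts), the cohort mean and SD of those
#' medians, the single-measurement absolute-agreement ICC with 95% CI and
#' p-value computed from the raw trial values, and SEM / MDC derived from
#' the trial-level SD. The limb symmetry index is computed per subject from
#' the medians (non-dominant over dominant) and summarised as mean and SD.
#' Group-average ICCs are reported for the acceleration- and angular
#' velocity-based parameter families (both limbs pooled).
#'
#' @param records Long data.frame: subject, limb, task, trial, parameter,
#'   value.
#' @param alpha Significance level for the ICC confidence interval.
#' @param mdc_z z-value for the MDC.
#' @param lsi_band Physiological LSI band, percent.
#' @param groups Named list of parameter groups for average ICCs.
#' @param limb_levels Length-2 character vector naming the dominant and
#'   non-dominant limb labels, in that order.
#' @return A `cohort_summary`: `summary`, `lsi`, `group_icc` data.frames.
#' @export
summarize_cohort <- function(records, alpha = 0.05, mdc_z = 1.96,
                             lsi_band = c(85, 115),
                             groups = list(
                               acceleration = c("RMSa_foot", "RMSa_leg"),
                               angular_velocity = c("RMSw_foot", "RMSw_leg",
                                                    "wpeak_foot", "wpeak_leg")),
                             limb_levels = c("dominant", "non-dominant")) {
  stopifnot(all(c("subject", "limb", "task", "trial", "parameter", "value")
                %in% names(records)))
  if (!nrow(records)) stop("no records", call. = FALSE)

  med <- stats::aggregate(value ~ subject + limb + task + parameter,
                          data = records, FUN = lower_median)
  conds <- unique(records[, c("task", "parameter", "limb")])
  rows <- list(); lsirows <- list()
  for (j in seq_len(nrow(conds))) {
    tk <- conds$task[j]; pr <- conds$parameter[j]; lb <- conds$limb[j]
    mm <- med$value[med$task == tk & med$parameter == pr & med$limb == lb]
    sub <- records[records$task == tk & records$parameter == pr &
                     records$limb == lb, ]
    res <- tryCatch(
      icc_absolute_agreement(trial_matrix(sub, pr), alpha = alpha,
                             mdc_z = mdc_z),
      error = function(e) NULL)
    rows[[j]] <- data.frame(
      task = tk, parameter = pr, limb = lb,
      mean = mean(mm), sd = stats::sd(mm),
      icc = if (is.null(res)) NA_real_ else res$icc,
      ci_low = if (is.null(res)) NA_real_ else res$ci_low,
      ci_high = if (is.null(res)) NA_real_ else res$ci_high,
      p = if (is.null(res)) NA_real_ else res$p,
      sem = if (is.null(res)) NA_real_ else res$sem,
      mdc = if (is.null(res)) NA_real_ else res$mdc,
      n = length(mm), stringsAsFactors = FALSE)
  }
  summary_df <- do.call(rbind, rows)

  lsi_df <- NULL
  if (all(limb_levels %in% records$limb)) {
    wide <- merge(
      med[med$limb == limb_levels[1], c("subject", "task", "parameter", "value")],
      med[med$limb == limb_levels[2], c("subject", "task", "parameter", "value")],
      by = c("subject", "task", "parameter"), suffixes = c(".dom", ".nondom"))
    wide <- wide[wide$value.dom != 0, ]
    if (nrow(wide)) {
      wide$lsi <- wide$value.nondom / wide$value.dom * 100
      lsi_df <- stats::aggregate(lsi ~ task + parameter, data = wide,
        FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                            physiological = mean(v >= lsi_band[1] &
                                                   v <= lsi_band[2])))
      lsi_df <- cbind(lsi_df[c("task", "parameter")],
                      as.data.frame(lsi_df$lsi))
    }
  }

  gi <- list()
  for (tk in unique(summary_df$task)) {
    for (gn in names(groups)) {
      d <- summary_df[summary_df$task == tk &
                        summary_df$parameter %in% groups[[gn]] &
                        !is.na(summary_df$icc), ]
      if (nrow(d))
        gi[[length(gi) + 1L]] <- data.frame(task = tk, group = gn,
                                            icc = mean(d$icc),
                                            n_cells = nrow(d),
                                            stringsAsFactors = FALSE)
    }
  }
  structure(list(summary = summary_df, lsi = lsi_df,
                 group_icc = if (length(gi)) do.call(rbind, gi) else NULL),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$summary, digits = 3)
  if (!is.null(x$group_icc)) {
    cat("group-average ICC:\n")
    print(x$group_icc, digits = 3)
  }
  invisible(x)
}
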