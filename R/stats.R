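# Validation statistics: Pearson correlation / linear regression,
# vBMD-vs-age trends with a %/year loss rate, ICC(3,1) consistency
# reliability, phantom difference summaries, and a synthetic clinical
# cohort generator.

#' Linear fit with Pearson correlation
#'
#' Least-squares regression of `y` on `x` with the Pearson correlation
#' coefficient and its two-sided p-value (t distribution, n - 2 df).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return An object of class `regression_result`: list with `slope`,
#'   `intercept`, `pearson_r`, `p_value`, `n`.
#' @export
pearson_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("inputs must be finite")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = length(x)),
            class = "regression_result")
}

#' Age trend of vBMD with a percentage loss rate
#'
#' Regresses vBMD (g/cm^3) on age (years), optionally within one sex, and
#' expresses the slope as a loss rate in percent per year. The baseline
#' dividing the slope is the group mean vBMD by default
#' (`loss_rate = -slope / mean(vbmd) * 100`); alternatively the fitted
#' vBMD at the group's minimum age can be used.
#'
#' @param records data frame with columns `age`, `vbmd` and (if filtering)
#'   `sex` with values `"male"`/`"female"`.
#' @param sex optional filter, `"male"` or `"female"`.
#' @param baseline `"mean"` (group mean vBMD) or `"min_age"` (fitted value
#'   at the youngest age).
#' @return List with `fit` (a [pearson_fit()] result),
#'   `loss_rate_pct_per_year`, `baseline_vbmd`, `n`, `sex`.
#' @export
age_trend <- function(records, sex = NULL, baseline = c("mean", "min_age")) {
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(records), all(c("age", "vbmd") %in% names(records)))
  if (!is.null(sex)) {
    stopifnot("sex" %in% names(records))
    records <- records[records$sex == sex, , drop = FALSE]
  }
  if (nrow(records) < 3L) stop("need at least 3 records after filtering")
  if (any(records$age <= 0)) stop("ages must be positive")
  fit <- pearson_fit(records$age, records$vbmd)
  base <- if (baseline == "mean") mean(records$vbmd) else
    fit$intercept + fit$slope * min(records$age)
  if (base <= 0) stop("non-positive baseline vBMD; loss rate undefined")
  list(fit = fit,
       loss_rate_pct_per_year = -fit$slope / base * 100,
       baseline_vbmd = base, baseline = baseline,
       n = fit$n, sex = if (is.null(sex)) "all" else sex)
}

#' Intraclass correlation ICC(3,1), consistency definition
#'
#' Two-way mixed model, single measurement, consistency: raters are fixed,
#' subjects random, and systematic rater offsets do not count as
#' disagreement. From the two-way ANOVA mean squares (BMS between
#' subjects, EMS residual),
#' \deqn{ICC(3,1) = \frac{BMS - EMS}{BMS + (k-1)\,EMS},}
#' with the 95% confidence interval from the F-bounds on BMS/EMS
#' (Shrout–Fleiss construction): with `F0 = BMS/EMS`,
#' `FL = F0 / qF(0.975; n-1, (n-1)(k-1))`,
#' `FU = F0 * qF(0.975; (n-1)(k-1), n-1)`, and each bound mapped through
#' `(F - 1) / (F + k - 1)`.
#'
#' @param ratings numeric matrix or data frame, subjects in rows, raters in
#'   columns; complete (no missing cells), >= 5 subjects, >= 2 raters.
#' @param conf confidence level, default 0.95.
#' @return An object of class `icc_result`: list with `icc`, `ci95`,
#'   `model` (`"ICC(3,1) consistency"`), `k_raters`, `n_subjects`, and the
#'   mean squares `bms`, `ems`.
#' @export
icc_consistency <- function(ratings, conf = 0.95) {
  m <- as.matrix(ratings)
  if (!is.numeric(m)) stop("ratings must be numeric")
  if (anyNA(m)) stop("ratings table has missing cells; no imputation is done")
  n <- nrow(m); k <- ncol(m)
  if (n < 5L) stop("need at least 5 subjects, got ", n)
  if (k < 2L) stop("need at least 2 raters, got ", k)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  resid <- m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand
  ems <- sum(resid^2) / ((n - 1) * (k - 1))
  if (bms <= 0) stop("no between-subject variance; ICC undefined")
  if (ems <= .Machine$double.eps * bms) {
    icc <- 1; ci <- c(1, 1)
  } else {
    icc <- (bms - ems) / (bms + (k - 1) * ems)
    alpha <- 1 - conf
    f0 <- bms / ems
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- f0 / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f0 * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci95 = ci, model = "ICC(3,1) consistency",
                 k_raters = k, n_subjects = n, bms = bms, ems = ems,
                 conf = conf),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result> ", x$model, ": ", round(x$icc, 3), " (",
      round(x$conf * 100), "% CI ", round(x$ci95[1], 3), "-",
      round(x$ci95[2], 3), "), n = ", x$n_subjects, " subjects x ",
      x$k_raters, " raters\n", sep = "")
  invisible(x)
}

#' Phantom recovery difference summary
#'
#' Per-item signed differences (calculated - real) between nominal and
#' recovered vBMD values, with the mean and maximum absolute difference —
#' the error summary used for vial-array validation.
#'
#' @param real,calculated numeric vectors of equal length >= 1, g/cm^3.
#' @return An object of class `difference_summary`: list with
#'   `per_item_diff`, `mean_abs_diff`, `max_abs_diff`.
#' @export
difference_summary <- function(real, calculated) {
  stopifnot(is.numeric(real), is.numeric(calculated))
  if (length(real) != length(calculated)) {
    stop("length mismatch: ", length(real), " vs ", length(calculated))
  }
  if (length(real) < 1L) stop("need at least one pair")
  d <- calculated - real
  structure(list(per_item_diff = d,
                 mean_abs_diff = mean(abs(d)),
                 max_abs_diff = max(abs(d))),
            class = "difference_summary")
}

#' Simulate a clinical QCT/DXA cohort
#'
#' Generates subject records (id, sex, age, DXA aBMD, femoral-neck vBMD)
#' with linear age trends and Gaussian scatter. Defaults emulate a
#' retrospective cohort of 17 males (ages 30–69) and 11 females (ages
#' 34–59) with mean vBMD 0.166 g/cm^3 and mean aBMD 0.892 g/cm^2, a female
#' loss rate near 0.9 %/year and a male rate near 0.3 %/year, and an
#' aBMD–vBMD correlation near 0.92. Ground truth is returned in the
#' attributes so parameter-recovery tests can compare against it.
#'
#' @param n_male,n_female group sizes.
#' @param age_range_male,age_range_female uniform age ranges, years.
#' @param mean_vbmd cohort mean vBMD at the group mean age, g/cm^3.
#' @param loss_rate_male,loss_rate_female true loss rates, %/year, applied
#'   to `mean_vbmd` to set the age slopes.
#' @param resid_sd_male,resid_sd_female residual vBMD SD about the age
#'   trend, g/cm^3.
#' @param mean_abmd,sd_abmd,abmd_r aBMD marginal mean/SD (g/cm^2) and its
#'   target correlation with vBMD.
#' @param seed RNG seed.
#' @return Data frame with columns `id`, `sex`, `age`, `abmd`, `vbmd`;
#'   attribute `truth` records the generating parameters.
#' @export
simulate_cohort <- function(n_male = 17, n_female = 11,
                            age_range_male = c(30, 69),
                            age_range_female = c(34, 59),
                            mean_vbmd = 0.166,
                            loss_rate_male = 0.290,
                            loss_rate_female = 0.898,
                            resid_sd_male = 0.024,
                            resid_sd_female = 0.0138,
                            mean_abmd = 0.892, sd_abmd = 0.130,
                            abmd_r = 0.920, seed = 1L) {
  slope_m <- -loss_rate_male / 100 * mean_vbmd
  slope_f <- -loss_rate_female / 100 * mean_vbmd
  with_seed(seed, {
    age_m <- stats::runif(n_male, age_range_male[1], age_range_male[2])
    age_f <- stats::runif(n_female, age_range_female[1], age_range_female[2])
    vbmd_m <- mean_vbmd + slope_m * (age_m - mean(age_range_male)) +
      stats::rnorm(n_male, 0, resid_sd_male)
    vbmd_f <- mean_vbmd + slope_f * (age_f - mean(age_range_female)) +
      stats::rnorm(n_female, 0, resid_sd_female)
    vbmd <- pmax(c(vbmd_m, vbmd_f), 0.05)
    sd_v <- 0.025   # nominal cohort vBMD SD used to scale the aBMD link
    b <- abmd_r * sd_abmd / sd_v
    abmd <- mean_abmd + b * (vbmd - mean_vbmd) +
      stats::rnorm(n_male + n_female, 0, sd_abmd * sqrt(1 - abmd_r^2))
    out <- data.frame(
      id = sprintf("S%02d", seq_len(n_male + n_female)),
      sex = c(rep("male", n_male), rep("female", n_female)),
      age = c(age_m, age_f),
      abmd = pmax(abmd, 0.1),
      vbmd = vbmd)
    attr(out, "truth") <- list(
      slope_male = slope_m, slope_female = slope_f,
      loss_rate_male = loss_rate_male, loss_rate_female = loss_rate_female,
      mean_vbmd = mean_vbmd, abmd_r = abmd_r, seed = seed)
    out
  })
}
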