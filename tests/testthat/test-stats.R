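test_that("pearson_fit matches hand-computed correlations", {
  x <- 1:10
  f <- pearson_fit(x, 2 * x + 1)
  expect_equal(f$pearson_r, 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)

  # constructed orthogonal residuals
  expect_equal(pearson_fit(c(1, 2, 3), c(1, -2, 1))$pearson_r, 0)

  f5 <- pearson_fit(1:5, c(2, 1, 4, 3, 5))
  expect_equal(f5$pearson_r, 0.8)
  expect_equal(f5$n, 5L)
  expect_true(f5$p_value > 0 && f5$p_value < 1)

  expect_error(pearson_fit(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_fit(1:4, 1:5), "equal length")
  expect_error(pearson_fit(1:2, 1:2), "at least 3")
})

test_that("Pearson r is invariant under positive affine transforms", {
  set.seed(3)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  r0 <- pearson_fit(x, y)$pearson_r
  expect_equal(pearson_fit(3 * x + 7, y)$pearson_r, r0, tolerance = 1e-12)
  expect_equal(pearson_fit(x, 0.1 * y - 2)$pearson_r, r0, tolerance = 1e-12)
})

test_that("age_trend converts the slope into a %/year loss rate", {
  ages <- c(40, 45, 50, 55, 60)
  rec <- data.frame(age = ages, vbmd = 0.166 - 0.0015 * (ages - 50))
  tr <- age_trend(rec)
  expect_equal(tr$fit$slope, -0.0015, tolerance = 1e-12)
  expect_equal(tr$baseline_vbmd, 0.166)
  expect_equal(tr$loss_rate_pct_per_year, 0.0015 / 0.166 * 100,
               tolerance = 1e-9)   # 0.9036...
  # exactly flat trend: zero loss rate
  flat <- data.frame(age = 1:4, vbmd = c(0.1, 0.2, 0.2, 0.1))
  expect_equal(age_trend(flat)$loss_rate_pct_per_year, 0)
})

test_that("regression recovers the generating slope on synthetic cohorts", {
  # cohorts large enough that +/- 2 SE carries ~95% coverage under the t
  truth <- attr(simulate_cohort(seed = 1), "truth")
  hits <- 0L
  for (k in 1:100) {
    coh <- simulate_cohort(n_male = 40, n_female = 40, seed = 1000 + k)
    fem <- coh[coh$sex == "female", ]
    fit <- lm(vbmd ~ age, data = fem)
    se <- summary(fit)$coefficients["age", "Std. Error"]
    if (abs(coef(fit)[["age"]] - truth$slope_female) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits, 93L)
})

test_that("ICC(3,1) consistency is exact in the degenerate cases", {
  v <- c(0.11, 0.15, 0.13, 0.19, 0.16, 0.12)
  expect_equal(icc_consistency(cbind(v, v))$icc, 1)
  # a fixed rater offset is not disagreement under the consistency definition
  res <- icc_consistency(cbind(v, v + 0.05))
  expect_equal(res$icc, 1)
  expect_equal(res$ci95, c(1, 1))
  expect_error(icc_consistency(cbind(c(v, NA), c(v, 0.1))), "missing")
  expect_error(icc_consistency(cbind(v[1:4], v[1:4] + 0.01)), "at least 5")
})

test_that("ICC(3,1) matches an independent two-way ANOVA oracle", {
  set.seed(5)
  m <- matrix(rnorm(12, mean = 0.15, sd = 0.03), 6, 2)
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(seq_len(6), 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  bms <- ms[1]; ems <- ms[3]; k <- 2
  oracle <- (bms - ems) / (bms + (k - 1) * ems)
  res <- icc_consistency(m)
  expect_equal(res$icc, oracle, tolerance = 1e-10)
  expect_true(res$ci95[1] <= res$icc && res$icc <= res$ci95[2])
})

test_that("ICC(3,1) is invariant to per-rater offsets and global rescaling", {
  set.seed(8)
  m <- matrix(rnorm(24, 0.16, 0.02), 8, 3)
  base <- icc_consistency(m)$icc
  shifted <- sweep(m, 2, c(0.3, -0.2, 0.05), `+`)
  expect_equal(icc_consistency(shifted)$icc, base, tolerance = 1e-12)
  expect_equal(icc_consistency(m * 2.5)$icc, base, tolerance = 1e-12)
})

test_that("difference_summary reproduces the vial validation arithmetic", {
  expect_equal(difference_summary(vials_real, vials_real)$max_abs_diff, 0)
  ds <- difference_summary(vials_real, vials_calc)
  expect_equal(ds$max_abs_diff, 0.019)
  expect_equal(round(ds$mean_abs_diff, 3), 0.009)
  expect_equal(ds$per_item_diff, vials_calc - vials_real)
  expect_gte(ds$max_abs_diff, ds$mean_abs_diff)

  single <- difference_summary(0.1, 0.12)
  expect_equal(single$mean_abs_diff, 0.02)
  expect_equal(single$max_abs_diff, 0.02)
  expect_error(difference_summary(1:3, 1:2), "length mismatch")
})

test_that("simulate_cohort is reproducible and carries its ground truth", {
  a <- simulate_cohort(seed = 7)
  b <- simulate_cohort(seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(a), 28L)
  expect_equal(sum(a$sex == "male"), 17L)
  tr <- attr(a, "truth")
  expect_equal(tr$loss_rate_female, 0.898)
  expect_true(all(a$vbmd > 0) && all(a$abmd > 0))
})
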