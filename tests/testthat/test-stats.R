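test_that("LME recovers an injected condition effect with calibrated CIs", {
  covered <- logical(40)
  inside_own_ci <- logical(40)
  for (r in seq_len(40)) {
    cc <- mk_measurement_cohort(
      20, 20, seed = 500 + r,
      config = cohort_config(td_mean = c(`450` = -1, `900` = -1, `1800` = -1),
                             cln3_mean = c(`450` = -1, `900` = -1, `1800` = -1),
                             td_age_slope = 0, cln3_age_slope = 0,
                             stage_slope = 0, between_sd = 0.5))
    fit <- fit_mmn_lme(amplitude_long_table(cc$measurements),
                       covariate = "group", compare_age = FALSE)
    row <- fit$coefficients[fit$coefficients$term == "conditionDEV", ]
    covered[r] <- row$ci_lo <= -1 && -1 <= row$ci_hi
    inside_own_ci[r] <- row$ci_lo <= row$beta && row$beta <= row$ci_hi
  }
  expect_true(all(inside_own_ci))
  expect_gte(mean(covered), 0.9)
})

test_that("null effects rarely reach |t| > 2 in the LME", {
  n_rep <- 30
  tmat <- NULL
  for (r in seq_len(n_rep)) {
    cc <- mk_measurement_cohort(
      12, 12, seed = 900 + r,
      config = cohort_config(td_mean = c(`450` = 0, `900` = 0, `1800` = 0),
                             cln3_mean = c(`450` = 0, `900` = 0, `1800` = 0),
                             td_age_slope = 0, cln3_age_slope = 0,
                             stage_slope = 0, between_sd = 0.5))
    fit <- fit_mmn_lme(amplitude_long_table(cc$measurements),
                       covariate = "group", compare_age = FALSE)
    tv <- abs(fit$coefficients$t[-1])    # drop the intercept
    tmat <- rbind(tmat, tv)
  }
  calm_rate_per_term <- colMeans(tmat < 2)
  expect_true(all(calm_rate_per_term >= 0.9))
})

test_that("degenerate designs are refused with informative errors", {
  cc <- mk_measurement_cohort(3, 3, seed = 2)
  tbl <- amplitude_long_table(cc$measurements)
  expect_error(fit_mmn_lme(tbl[tbl$subject_id == tbl$subject_id[1], ]),
               "2 subjects")
  expect_error(fit_mmn_lme(tbl[tbl$condition == "DEV", ]), "both tone conditions")
  expect_error(fit_mmn_lme(tbl[, setdiff(names(tbl), "age")]), "missing columns")
})

test_that("stage-covariate model shape fits CLN3-only tables", {
  cc <- mk_measurement_cohort(0, 15, seed = 3)
  tbl <- amplitude_long_table(cc$measurements)
  fit <- fit_mmn_lme(tbl, covariate = "stage", compare_age = FALSE)
  expect_true(any(grepl("stage", fit$coefficients$term)))
})

test_that("planned contrast handles identical and zero-variance inputs", {
  meas <- data.frame(subject_id = sprintf("s%d", 1:10), soa = 900,
                     amp_dev = 1:10, amp_std = 1:10)
  res <- planned_mmn_contrast(meas, soa = 900, alternative = "two.sided")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  meas2 <- meas; meas2$amp_dev <- meas$amp_std + 1
  expect_warning(res2 <- planned_mmn_contrast(meas2, soa = 900,
                                              alternative = "two.sided"),
                 "infinite")
  expect_equal(res2$p, 0)
})

test_that("planned contrast detects the injected CLN3 900 ms MMN with power", {
  sig <- vapply(1:40, function(r) {
    cc <- mk_measurement_cohort(0, 21, seed = 1200 + r, meas_sd = 0.3)
    ct <- planned_mmn_contrast(cc$measurements, "CLN3", 900)
    ct$p < 0.05
  }, logical(1))
  expect_gte(mean(sig), 0.8)
})

test_that("Spearman bootstrap is rank-exact on monotone data, outlier-proof", {
  x <- 1:20
  r <- robust_spearman_bootstrap(x, exp(x / 3), seed = 7)
  expect_equal(r$rs, 1)
  expect_true(r$significant)

  set.seed(8)
  x2 <- 1:30; y2 <- x2 + stats::rnorm(30, 0, 3)
  ## two versions whose y ranks are identical but whose top value differs by 1e6
  y_mild <- y2; y_mild[30] <- max(y2) + 1
  y_extreme <- y2; y_extreme[30] <- max(y2) + 1e6
  r_mild <- robust_spearman_bootstrap(x2, y_mild, seed = 9)
  r_extreme <- robust_spearman_bootstrap(x2, y_extreme, seed = 9)
  expect_equal(r_extreme$rs, r_mild$rs)
  expect_gte(r_extreme$flagged_outliers, 1)
})

test_that("bootstrap CI covers zero for independent variables at nominal rate", {
  cover <- vapply(1:200, function(r) {
    set.seed(3000 + r)
    x <- stats::rnorm(40); y <- stats::rnorm(40)
    ci <- robust_spearman_bootstrap(x, y, n_boot = 300, seed = 4000 + r)$ci95
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  ## binomial tolerance around 0.95 over 200 reps (3 SE)
  expect_gt(mean(cover), 0.95 - 3 * sqrt(0.95 * 0.05 / 200))
})

test_that("Spearman estimate is invariant under strictly monotone transforms", {
  set.seed(10)
  x <- stats::rnorm(25); y <- x + stats::rnorm(25)
  r0 <- robust_spearman_bootstrap(x, y, seed = 11)$rs
  expect_equal(robust_spearman_bootstrap(exp(x), y, seed = 11)$rs, r0)
  expect_equal(robust_spearman_bootstrap(x, y^3 + 5 * y, seed = 11)$rs, r0)
})
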