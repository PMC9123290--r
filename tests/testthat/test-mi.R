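test_that("Rubin's rules match hand computation", {
  two <- list(list(coef = c(b = 1), se = c(b = 1)),
              list(coef = c(b = 3), se = c(b = 1)))
  p <- pool_estimates(two)
  expect_equal(p$qbar, 2)
  expect_equal(p$W, 1)
  expect_equal(p$B, 2)
  expect_equal(p$T, 1 + 1.5 * 2)       # W + (1 + 1/m) B with m = 2
  expect_equal(p$df, (2 - 1) * (1 + 1 / ((1 + 1 / 2) * 2))^2)

  same <- replicate(5, list(coef = c(b = 2), se = c(b = 0.5)),
                    simplify = FALSE)
  p0 <- pool_estimates(same)
  expect_equal(p0$qbar, 2)
  expect_equal(p0$B, 0)
  expect_equal(p0$T, 0.25)             # T = W when B = 0
  expect_equal(p0$df, Inf)

  expect_error(pool_estimates(list(list(coef = c(b = 1), se = c(b = 1)))),
               "m >= 2")
  expect_error(pool_estimates(list()), "no estimates")
})

test_that("pooled intervals are never narrower than within-imputation ones", {
  set.seed(41)
  ests <- lapply(1:10, function(i)
    list(coef = c(a = rnorm(1), b = rnorm(1)), se = c(a = 0.3, b = 0.8)))
  p <- pool_estimates(ests)
  expect_true(all(p$T >= p$W))
  expect_true(all(p$se >= sqrt(p$W)))
})

test_that("imputation completes MAR-degraded cohorts and preserves observed cells", {
  co <- generate_cohort(cohort_config(seed = 11, missing_rate = 0.28))
  imp <- impute_cohorts(co, m = 3, seed = 2)
  expect_length(imp, 3)
  for (d in imp) {
    for (cc in genderwork:::imputable_columns()) {
      expect_false(anyNA(d[[cc]]))
      obs <- !is.na(co[[cc]])
      expect_identical(d[[cc]][obs], co[[cc]][obs])
    }
  }
  # types survive: integer scores stay integer, education keeps its levels
  expect_true(is.integer(imp[[1]]$cesd))
  expect_equal(levels(imp[[1]]$education), c("low", "intermediate", "high"))
  expect_true(all(imp[[1]]$cesd %in% 0:60))
  # different imputations differ where cells were missing
  mis <- is.na(co$cesd)
  expect_false(identical(imp[[1]]$cesd[mis], imp[[2]]$cesd[mis]))
})

test_that("complete data yield identical copies; edge cases error or warn", {
  co <- generate_cohort(cohort_config(n = 80, seed = 5))
  imp <- impute_cohorts(co, m = 4, seed = 1)
  expect_length(imp, 4)
  for (d in imp) expect_identical(d, co)

  co2 <- generate_cohort(cohort_config(n = 80, seed = 5, missing_rate = 0.2))
  expect_warning(impute_cohorts(co2, m = 1, seed = 1), "m = 1")
  co3 <- co2
  co3$cesd <- NA_integer_
  expect_error(impute_cohorts(co3, m = 2, seed = 1), "100% missing")
})

test_that("pooled tobit recovers the gender effect under 28% MAR missingness", {
  # scaled-down calibration check: 20 replicates, m = 10 imputations
  covered <- 0L
  for (r in 1:20) {
    oc <- genderwork:::default_outcome_coefs()
    oc$wc[] <- 0  # total feminine effect equals the direct coefficient 1.85
    cfg <- cohort_config(seed = 3000L + r, missing_rate = 0.28,
                         outcome_coefs = oc)
    co <- generate_cohort(cfg)
    imp <- impute_cohorts(co, m = 10, seed = 300L + r)
    ests <- lapply(imp, function(d) {
      idx <- build_gender_index(d, cutoff = 7)
      X <- cbind(1, feminine = as.numeric(idx$gender_binary == "feminine"),
                 age = d$age - mean(d$age))
      fit <- suppressWarnings(fit_tobit(X, d$cesd))
      list(coef = fit$coefficients["feminine"], se = fit$se["feminine"])
    })
    p <- pool_estimates(ests)
    if (abs(p$qbar - 1.85) <= 3 * p$se) covered <- covered + 1L
  }
  expect_gte(covered, 18L)
})
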