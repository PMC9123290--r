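test_that("generator reproduces sample size, sex mix and seeded determinism", {
  cfg <- cohort_config(seed = 1)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co), 313L)
  # binomial 99% bounds around the configured female share
  half_width <- qnorm(0.995) * sqrt(0.435 * 0.565 / 313)
  expect_lt(abs(mean(co$sex == "female") - 0.435), half_width)
  expect_true(all(co$cesd >= 0 & co$cesd <= 60))
  expect_true(all(co$pct_female_sector >= 0 & co$pct_female_sector <= 100))

  one <- generate_cohort(cohort_config(n = 1, p_female = 0))
  expect_equal(nrow(one), 1L)
  expect_equal(as.character(one$sex), "male")

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(cohort_config(seed = 7)), f1)
  write_cohort(generate_cohort(cohort_config(seed = 7)), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(file.exists(paste0(f1, ".config.json")))
})

test_that("invalid configurations are rejected with the offending field named", {
  ip <- genderwork:::default_item_probs()
  ip$chores$probs["female", 1] <- ip$chores$probs["female", 1] + 0.05
  expect_error(cohort_config(item_probs = ip), "chores.*female")
  expect_error(cohort_config(sigma = -1), "sigma")
  expect_error(cohort_config(missing_rate = 1), "missing_rate")
  expect_error(cohort_config(n = 0), "n must")
})

test_that("censoring fraction matches the normal mass below the rounding floor", {
  # intercept-only outcome: latent N(5.7, 5.6^2); rounding puts latent < 0.5
  # at the floor, so the expected share at zero is Phi((0.5 - 5.7)/5.6)
  cfg <- null_outcome_config(n = 20000L, seed = 3)
  co <- generate_cohort(cfg)
  frac <- censoring_fraction(co)
  expect_gt(frac, 0.05); expect_lt(frac, 0.35)
  oracle <- pnorm((0.5 - 5.7) / 5.6)
  expect_lt(abs(frac - oracle), 3 * sqrt(oracle * (1 - oracle) / 20000) + 0.005)

  hi <- generate_cohort(null_outcome_config(n = 200L, seed = 4, intercept = 100,
                                            sigma = 1))
  expect_equal(censoring_fraction(hi), 0)
  lo <- generate_cohort(null_outcome_config(n = 200L, seed = 4, intercept = -100,
                                            sigma = 1))
  expect_equal(censoring_fraction(lo), 1)

  co$cesd[c(2, 5)] <- NA
  expect_error(censoring_fraction(co), "2, 5")
})

test_that("generated CES-D converges to the censored-normal closed forms", {
  # enumeration oracle over the integer support, with rounding bands
  k <- 0:60
  pk <- pnorm((k + 0.5 - 5) / 5) - pnorm((k - 0.5 - 5) / 5)
  pk[1] <- pnorm(0.5, 5, 5)           # all latent below 0.5 rounds to 0
  pk[61] <- 1 - pnorm(59.5, 5, 5)
  mu <- sum(k * pk)
  sdv <- sqrt(sum((k - mu)^2 * pk))
  # standardized deviations pooled over independent cohorts, so the check
  # sits at 2 Monte-Carlo SEs of the combined sample
  z_mean <- z_sd <- numeric(3)
  for (i in 1:3) {
    cfg <- null_outcome_config(n = 50000L, seed = i, intercept = 5,
                               sigma = 5)
    co <- generate_cohort(cfg)
    n <- nrow(co)
    z_mean[i] <- (mean(co$cesd) - mu) / (sdv / sqrt(n))
    m4 <- mean((co$cesd - mean(co$cesd))^4)
    s <- sd(co$cesd)
    se_sd <- sqrt(max(m4 - s^4, 0) / (4 * s^2 * n))
    z_sd[i] <- (s - sdv) / se_sd
  }
  expect_lt(abs(sum(z_mean)) / sqrt(3), 2)
  expect_lt(abs(sum(z_sd)) / sqrt(3), 2)
})

test_that("null-effect generator induces no sex association with CES-D", {
  hits <- 0L
  for (r in 1:200) {
    co <- generate_cohort(null_outcome_config(n = 200L, seed = 5000L + r))
    X <- cbind(1, female = as.numeric(co$sex == "female"),
               age = co$age - mean(co$age))
    fit <- suppressWarnings(fit_tobit(X, co$cesd))
    ci <- confint(fit)["female", ]
    if (ci[1] <= 0 && ci[2] >= 0) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.93)
})

test_that("MAR degradation is calibrated and never alters observed cells", {
  cfg <- cohort_config(seed = 21, missing_rate = 0.28)
  co <- generate_cohort(cfg)
  complete <- attr(co, "truth")$complete
  cols <- genderwork:::imputable_columns()
  vals <- unlist(lapply(cols, function(cc) is.na(co[[cc]])))
  expect_lt(abs(mean(vals) - 0.28), 0.03)
  for (cc in cols) {
    obs <- !is.na(co[[cc]])
    expect_identical(co[[cc]][obs], complete[[cc]][obs])
  }
  expect_false(anyNA(co$sex))
  expect_false(anyNA(co$age))
  # missingness depends on sex (the MAR driver)
  miss_rate <- tapply(is.na(co$cesd), co$sex, mean)
  expect_gt(miss_rate["female"], miss_rate["male"] - 0.02)
})

test_that("cohort CSV round-trips with missing values as empty fields", {
  co <- generate_cohort(cohort_config(n = 60, seed = 2, missing_rate = 0.2))
  f <- tempfile(fileext = ".csv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(back$cesd, co$cesd)
  expect_equal(levels(back$education), c("low", "intermediate", "high"))
  expect_equal(back$hours_per_week, co$hours_per_week, tolerance = 1e-12)
  cfg <- jsonlite::read_json(paste0(f, ".config.json"))
  expect_equal(cfg$seed, 2L)
})
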