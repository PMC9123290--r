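test_that("indirect effect is the product of path and probability contrast", {
  # logistic with p(T=1) = 0.25, p(T=0) = 0.5 at age 0: contrast -0.25
  a_fit <- forge_logistic(c(0, qlogis(0.25), 0))
  b_fit <- forge_tobit(c(0, -2, 0, 0), sigma = 1)
  expect_equal(acme_binary_mediator(a_fit, b_fit, rep(0, 10)), 0.5)
  # zero a-path slope: indirect effect exactly zero regardless of ages
  a_null <- forge_logistic(c(0.3, 0, 0.1))
  expect_identical(acme_binary_mediator(a_null, b_fit, rnorm(10)), 0)
})

test_that("expected-scale indirect effect shrinks toward the latent one", {
  co <- generate_cohort(mediation_truth_config(n = 2000, seed = 31))
  lat <- mediate(co, "gender", "autonomy", n_boot = 1, seed = 1,
                 cutoff = 7, scale = "latent")
  exp_scale <- mediate(co, "gender", "autonomy", n_boot = 1, seed = 1,
                       cutoff = 7, scale = "expected")
  expect_equal(sign(lat$acme), sign(exp_scale$acme))
  expect_lt(abs(exp_scale$acme), abs(lat$acme))  # censoring attenuates
})

test_that("recoding the mediator flips a and b paths and preserves the ACME", {
  co <- generate_cohort(mediation_truth_config(n = 800, seed = 17))
  d <- genderwork:::prepare_paths(co, "gender", "autonomy", cutoff = 7)
  f1 <- genderwork:::fit_paths(d)
  a1 <- acme_binary_mediator(f1$a, f1$bc, d$age)
  d2 <- d; d2$m <- 1L - d$m
  f2 <- genderwork:::fit_paths(d2)
  a2 <- acme_binary_mediator(f2$a, f2$bc, d2$age)
  expect_equal(a2, a1, tolerance = 1e-6)
  expect_equal(unname(f2$a$coefficients["exposure"]),
               -unname(f1$a$coefficients["exposure"]), tolerance = 1e-6)
  expect_equal(unname(f2$bc$coefficients["mediator"]),
               -unname(f1$bc$coefficients["mediator"]), tolerance = 1e-5)
})

test_that("bootstrap is seeded, reproducible, and degenerate at one resample", {
  co <- generate_cohort(cohort_config(n = 200, seed = 6))
  m1 <- mediate(co, "sex", "variation", n_boot = 25, seed = 9)
  m2 <- mediate(co, "sex", "variation", n_boot = 25, seed = 9)
  expect_identical(m1$acme_boot, m2$acme_boot)
  expect_identical(m1$acme_ci, m2$acme_ci)

  m_one <- mediate(co, "sex", "variation", n_boot = 1, seed = 2)
  expect_equal(m_one$acme_ci[1], m_one$acme_ci[2])
  expect_equal(m_one$acme_ci[1], m_one$acme_boot[1])
})

test_that("moderation recovers a known interaction and rejects degenerate cells", {
  oc <- genderwork:::default_outcome_coefs()
  oc$interaction <- list(wc = "support", coef = 3)
  cfg <- cohort_config(n = 2000, seed = 12, outcome_coefs = oc, sigma = 4)
  co <- generate_cohort(cfg)
  mr <- test_moderation(co, "gender", "support", cutoff = 7)
  expect_lt(abs(mr$interaction$estimate - 3), 3 * mr$interaction$se)
  expect_lt(mr$interaction$p, 0.05)
  expect_equal(mr$group_label, "gender")

  co_small <- generate_cohort(cohort_config(n = 100, seed = 3))
  co_small$sex <- factor(rep("male", 100), levels = c("male", "female"))
  expect_error(test_moderation(co_small, "sex", "support"), "constant")
})

test_that("null generators keep the moderation interaction near zero", {
  hits <- 0L
  for (r in 1:200) {
    co <- generate_cohort(null_outcome_config(n = 250L, seed = 9000L + r,
                                              equal_wc = TRUE))
    mr <- suppressWarnings(test_moderation(co, "gender", "autonomy", cutoff = 7))
    if (mr$interaction$ci[1] <= 0 && mr$interaction$ci[2] >= 0) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.93)
})
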