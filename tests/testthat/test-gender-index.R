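test_that("income equivalization scales partnered households by 0.7", {
  expect_equal(equivalize_income(2000, TRUE), 1400)
  expect_equal(equivalize_income(2000, FALSE), 2000)
  expect_equal(equivalize_income(0, TRUE), 0)
  expect_equal(equivalize_income(c(1000, 1000), c(TRUE, FALSE)), c(700, 1000))
  expect_error(equivalize_income(-5, TRUE), "non-negative")
})

test_that("quartile coding matches a brute-force type-7 oracle", {
  expect_equal(quartile_codes(1:8), c(0L, 0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(quartile_codes(1:8, reversed = TRUE),
               c(3L, 3L, 2L, 2L, 1L, 1L, 0L, 0L))
  for (s in 1:5) {
    set.seed(s)
    v <- round(runif(23, 0, 50), 1)
    expect_equal(quartile_codes(v), quartile_codes_oracle(v))
    expect_equal(quartile_codes(v, TRUE), quartile_codes_oracle(v, TRUE))
  }
  expect_error(quartile_codes(rep(4, 10)), "degenerate")
  expect_error(quartile_codes(c(1, 2, 3)), "degenerate")
})

test_that("fixed-band item codes follow the published category bounds", {
  expect_equal(code_segregation(c(25, 26, 50, 51, 75, 76, 100)),
               c(0L, 1L, 1L, 2L, 2L, 3L, 3L))
  expect_error(code_segregation(101), "0, 100")
  expect_equal(code_education(c("high", "intermediate", "low")), c(0L, 1L, 2L))
  expect_error(code_education("phd"), "unknown")
  expect_equal(code_caregiving(c(0, 3, 7.9, 8, 12)), c(0L, 1L, 1L, 2L, 2L))
  expect_error(code_caregiving(-1), "non-negative")
})

test_that("median split dichotomizes above the median with ties going low", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(5, 5, 5, 6))),
               c("low", "low", "low", "high"))
  expect_error(median_split(1), "at least 2")
})

test_that("extreme profiles score 0 and 16 and split at the 7/8 boundary", {
  idx <- build_gender_index(profile_frame(), cutoff = 7)
  expect_equal(idx$gender_total[8], 0L)
  expect_equal(as.character(idx$gender_binary[8]), "masculine")
  expect_equal(idx$gender_total[1], 16L)
  expect_equal(as.character(idx$gender_binary[1]), "feminine")

  # rows engineered to total exactly 7 and 8: bottom-quartile hours/income
  # (3 + 3) plus segregation band 1 vs 2, everything else at 0
  d <- profile_frame()
  d$pct_female_sector <- c(40, 60, 60, 55, 40, 30, 20, 10)
  d$education <- factor(rep("high", 8), levels = levels(d$education))
  d$caregiving_hours_per_week <- rep(0, 8)
  d$chores_min_per_day <- 1:8
  idx <- build_gender_index(d, cutoff = 7)
  expect_equal(idx$gender_total[1:2], c(7L, 8L))
  expect_equal(as.character(idx$gender_binary[1:2]), c("masculine", "feminine"))
})

test_that("index construction is permutation invariant and item monotone", {
  co <- generate_cohort(cohort_config(n = 120, seed = 14))
  idx <- build_gender_index(co, cutoff = 7)
  perm <- sample(nrow(co))
  idx_p <- build_gender_index(co[perm, ], cutoff = 7)
  expect_equal(idx_p$gender_total, idx$gender_total[perm])
  expect_equal(as.character(idx_p$gender_binary),
               as.character(idx$gender_binary)[perm])

  # pushing single raw items in the feminine direction never lowers a total
  bump <- function(col, value, i = 5L) {
    co2 <- co
    co2[[col]][i] <- value
    build_gender_index(co2, cutoff = 7)$gender_total[i]
  }
  base <- idx$gender_total[5]
  expect_gte(bump("caregiving_hours_per_week", 12), base)
  expect_gte(bump("chores_min_per_day", max(co$chores_min_per_day) + 1), base)
  expect_gte(bump("hours_per_week", 1), base)         # reversed item
  expect_gte(bump("pct_female_sector", 95), base)
  expect_gte(bump("education", "low"), base)
})

test_that("missing raw items are reported by record and item", {
  co <- generate_cohort(cohort_config(n = 50, seed = 3))
  co$chores_min_per_day[7] <- NA
  expect_error(build_gender_index(co), "chores_min_per_day.*7")
})

test_that("women are far more often classified feminine than men", {
  co <- generate_cohort(cohort_config(seed = 2))
  idx <- build_gender_index(co, cutoff = 7)
  fem <- idx$gender_binary == "feminine"
  p_w <- mean(fem[co$sex == "female"])
  p_m <- mean(fem[co$sex == "male"])
  expect_gt(p_w, 0.5)   # study sample: about 70% of women
  expect_lt(p_m, 0.4)   # study sample: about 18% of men
  expect_gt(p_w - p_m, 0.3)
})
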