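# simulated left-censored regression data with known truth
sim_tobit_data <- function(n, beta, sigma, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (length(beta) - 1L)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(length(beta) - 1L)))
  list(X = X, y = pmax(0, drop(X %*% beta) + rnorm(n, 0, sigma)),
       beta = beta, sigma = sigma)
}

# independent type-7 quantile: sort + linear interpolation at h = (n-1)p
quantile7_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p
  lo <- floor(h)
  s[lo + 1] + (h - lo) * (s[pmin(lo + 2, length(s))] - s[lo + 1])
}

# brute-force quartile coding: explicit band comparison, top band closed
quartile_codes_oracle <- function(values, reversed = FALSE) {
  q <- vapply(c(0.25, 0.5, 0.75), function(p) quantile7_oracle(values, p),
              numeric(1))
  code <- integer(length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    code[i] <- if (v < q[1]) 0L else if (v < q[2]) 1L else if (v < q[3]) 2L else 3L
  }
  if (reversed) 3L - code else code
}

# 8-person frame spanning all item codings; rows 1 and 8 are the extreme
# all-feminine and all-masculine profiles
profile_frame <- function() {
  data.frame(
    id = 1:8,
    sex = factor(rep(c("female", "male"), each = 4),
                 levels = c("male", "female")),
    age = rep(59, 8),
    hours_per_week = 1:8,                       # row 1 bottom quartile
    income_monthly = 1000 * (1:8),
    has_partner = rep(FALSE, 8),
    pct_female_sector = c(90, 80, 60, 55, 40, 30, 20, 10),
    education = factor(c("low", "low", "intermediate", "intermediate",
                         "high", "high", "high", "high"),
                       levels = c("low", "intermediate", "high")),
    caregiving_hours_per_week = c(10, 9, 5, 4, 0, 0, 0, 0),
    chores_min_per_day = 8:1                    # row 1 top quartile
  )
}

# forged path fits with exactly known coefficients, for closed-form checks
forge_logistic <- function(coefs) {
  structure(list(coefficients = coefs, se = rep(0.1, length(coefs)),
                 converged = TRUE, n = 0L),
            class = "logistic_fit")
}
forge_tobit <- function(coefs, sigma = 1) {
  structure(list(coefficients = coefs, sigma = sigma, converged = TRUE,
                 left_limit = 0),
            class = "tobit_fit")
}

# generator configuration with no sex/gender/working-condition effects
null_outcome_config <- function(n = 313L, seed = 1L, intercept = 5.7,
                                sigma = 5.6, equal_wc = FALSE, ...) {
  oc <- list(intercept = intercept, female = 0, feminine = 0,
             wc = stats::setNames(rep(0, 6), genderwork:::wc_names()),
             age = 0)
  args <- list(n = n, seed = seed, outcome_coefs = oc, sigma = sigma, ...)
  if (equal_wc) {
    wcp <- genderwork:::default_wc_prevalence()
    wcp$probs["masculine", ] <- 0.4
    wcp$probs["feminine", ] <- 0.4
    args$wc_prevalence <- wcp
  }
  do.call(cohort_config, args)
}

# configuration with a known exposure -> mediator -> outcome chain on one
# working condition (a-path log-odds and b-path on the latent scale)
mediation_truth_config <- function(n, seed, wc = "autonomy",
                                   a_logodds = 1, b_coef = -2,
                                   feminine = 1.85, sigma = 4) {
  wcp <- genderwork:::default_wc_prevalence()
  wcp$probs["masculine", wc] <- stats::plogis(-a_logodds / 2)
  wcp$probs["feminine", wc] <- stats::plogis(a_logodds / 2)
  oc <- genderwork:::default_outcome_coefs()
  oc$wc[] <- 0
  oc$wc[wc] <- b_coef
  oc$feminine <- feminine
  oc$female <- 0
  cohort_config(n = n, seed = seed, wc_prevalence = wcp,
                outcome_coefs = oc, sigma = sigma)
}

# closed-form indirect effect implied by mediation_truth_config
mediation_truth_acme <- function(a_logodds = 1, b_coef = -2) {
  b_coef * (stats::plogis(a_logodds / 2) - stats::plogis(-a_logodds / 2))
}
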