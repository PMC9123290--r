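#' Generate a synthetic cohort of older workers
#'
#' Draws `config$n` persons with sex, age, the six gender-role items (raw
#' scale), six working-condition sum scores and a follow-up CES-D total.
#' Generation proceeds in causal order:
#' \enumerate{
#'   \item sex, age, partner status;
#'   \item each gender item: a category is sampled from the sex-specific
#'     probability table, then a raw value uniformly inside that category's
#'     band (income is drawn on the equivalized scale and divided back by 0.7
#'     for partnered respondents, so the equivalization code path is
#'     genuinely exercised downstream);
#'   \item the feminine/masculine group is computed from the items with the
#'     fixed index cutoff `config$gender_cutoff`;
#'   \item each working condition: a latent "high" indicator with the
#'     group-specific prevalence, realized as an integer sum score placed at
#'     the condition's cut value (low, with small downward spread) or
#'     strictly above it (high), so a within-cohort median split recovers the
#'     configured prevalence;
#'   \item CES-D: `round(min(60, max(0, latent)))` with latent
#'     `= Xb + e`, `e ~ N(0, sigma)`, where `Xb` uses the outcome
#'     coefficients on sex, gender group, the six high indicators and
#'     centered age.
#' }
#' With `missing_rate > 0`, gender items, working-condition scores and CES-D
#' are degraded missing-at-random: cellwise Bernoulli with a logistic
#' probability in sex and standardized age whose marginal equals
#' `missing_rate`. Sex, age and partner status are never set missing, and
#' observed cells are never altered.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per person and columns `id`, `sex`,
#'   `age`, `hours_per_week`, `income_monthly`, `has_partner`,
#'   `pct_female_sector`, `education`, `caregiving_hours_per_week`,
#'   `chores_min_per_day`, `wc_physical` ... `wc_support`, `cesd`. The
#'   attributes `config` and `truth` (the generating feminine indicator,
#'   working-condition indicators and latent linear predictor, and the
#'   pre-degradation complete data) support calibration checks.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n

  sex <- factor(ifelse(stats::runif(n) < config$p_female, "female", "male"),
                levels = c("male", "female"))
  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  has_partner <- stats::runif(n) < config$p_partner

  draw_item <- function(spec) {
    cat_idx <- integer(n)
    for (s in c("male", "female")) {
      idx <- which(sex == s)
      if (length(idx)) {
        cat_idx[idx] <- sample.int(ncol(spec$probs), length(idx),
                                   replace = TRUE, prob = spec$probs[s, ])
      }
    }
    cat_idx
  }
  in_band <- function(cat_idx, bands) {
    lo <- bands[cat_idx, 1]
    hi <- bands[cat_idx, 2]
    lo + stats::runif(n) * (hi - lo)
  }

  ip <- config$item_probs
  hours <- in_band(draw_item(ip$hours), ip$hours$bands)
  income_eq <- in_band(draw_item(ip$income), ip$income$bands)
  income_monthly <- income_eq / ifelse(has_partner, 0.7, 1)
  education <- factor(ip$education$levels[draw_item(ip$education)],
                      levels = c("low", "intermediate", "high"))
  cg_cat <- draw_item(ip$caregiving)
  caregiving <- ifelse(cg_cat == 1L, 0, in_band(cg_cat, ip$caregiving$bands))
  chores <- in_band(draw_item(ip$chores), ip$chores$bands)
  segregation <- in_band(draw_item(ip$segregation), ip$segregation$bands)

  records <- data.frame(
    id = seq_len(n), sex = sex, age = age, hours_per_week = hours,
    income_monthly = income_monthly, has_partner = has_partner,
    pct_female_sector = segregation, education = education,
    caregiving_hours_per_week = caregiving, chores_min_per_day = chores
  )

  feminine <- if (n >= 4) {
    idx <- build_gender_index(records, cutoff = config$gender_cutoff)
    idx$gender_binary == "feminine"
  } else {
    rep(FALSE, n)  # quartile coding undefined for tiny cohorts
  }
  group <- ifelse(feminine, "feminine", "masculine")

  wcp <- config$wc_prevalence
  wc_high <- matrix(FALSE, n, ncol(wcp$probs),
                    dimnames = list(NULL, colnames(wcp$probs)))
  wc_scores <- matrix(0L, n, ncol(wcp$probs),
                      dimnames = list(NULL, colnames(wcp$probs)))
  for (j in colnames(wcp$probs)) {
    high <- stats::runif(n) < wcp$probs[cbind(group, j)]
    lo_spread <- sample(0:2, n, replace = TRUE, prob = c(0.75, 0.15, 0.10))
    hi_spread <- sample(0:2, n, replace = TRUE, prob = c(0.50, 0.30, 0.20))
    sc <- ifelse(high, wcp$cut[j] + 1L + hi_spread, wcp$cut[j] - lo_spread)
    sc <- pmin(pmax(sc, wcp$range[j, 1]), wcp$range[j, 2])
    wc_high[, j] <- high
    wc_scores[, j] <- as.integer(sc)
  }
  colnames(wc_scores) <- paste0("wc_", colnames(wc_scores))
  records <- cbind(records, as.data.frame(wc_scores))

  oc <- config$outcome_coefs
  lp <- oc$intercept +
    oc$female * (sex == "female") +
    oc$feminine * feminine +
    drop(wc_high %*% oc$wc[colnames(wc_high)]) +
    oc$age * (age - config$age_mean)
  if (!is.null(oc$interaction)) {
    lp <- lp + oc$interaction$coef * feminine * wc_high[, oc$interaction$wc]
  }
  latent <- lp + stats::rnorm(n, 0, config$sigma)
  records$cesd <- as.integer(round(pmin(60, pmax(0, latent))))

  complete <- records
  if (config$missing_rate > 0) {
    records <- degrade_mar(records, config)
  }

  attr(records, "config") <- config
  attr(records, "truth") <- list(feminine = feminine, wc_high = wc_high,
                                 linear_predictor = lp, complete = complete)
  records
}

# MAR cellwise degradation: logistic missingness probability in sex and
# standardized age, with the intercept solved so the marginal rate matches.
degrade_mar <- function(records, config) {
  lp <- 0.6 * (records$sex == "female") +
    0.4 * (records$age - config$age_mean) / config$age_sd
  f <- function(a) mean(stats::plogis(a + lp)) - config$missing_rate
  a <- stats::uniroot(f, c(-30, 30))$root
  p <- stats::plogis(a + lp)
  for (col in imputable_columns()) {
    mask <- stats::runif(nrow(records)) < p
    records[[col]][mask] <- NA
  }
  records
}

imputable_columns <- function() {
  c("hours_per_week", "income_monthly", "pct_female_sector", "education",
    "caregiving_hours_per_week", "chores_min_per_day",
    paste0("wc_", wc_names()), "cesd")
}

#' Fraction of CES-D scores at the censoring floor
#'
#' @param records Cohort data frame with a complete `cesd` column.
#' @return Proportion of records with `cesd == 0`, in `[0, 1]`.
#' @export
censoring_fraction <- function(records) {
  if (anyNA(records$cesd)) {
    ids <- if ("id" %in% names(records)) records$id[is.na(records$cesd)] else
      which(is.na(records$cesd))
    stop("cesd missing for record(s): ", paste(ids, collapse = ", "))
  }
  mean(records$cesd == 0)
}

#' Write / read a cohort as CSV with a JSON config sidecar
#'
#' Missing values are written as empty fields. `write_cohort()` also stores
#' the generating configuration (including the seed) as
#' `<path>.config.json` when the cohort carries one.
#'
#' @param records Cohort data frame.
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the cohort data frame with `sex` and `education` restored as factors.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  cfg <- attr(records, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  records <- utils::read.csv(path, na.strings = "")
  records$sex <- factor(records$sex, levels = c("male", "female"))
  records$education <- factor(records$education,
                              levels = c("low", "intermediate", "high"))
  if ("has_partner" %in% names(records)) {
    records$has_partner <- as.logical(records$has_partner)
  }
  records
}
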