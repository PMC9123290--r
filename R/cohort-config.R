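# Default per-sex category probabilities for the six gender-role items,
# expressed as percentages of each sex falling in each category, and the raw
# value band each category covers. The working-hours Q4 male/female cells are
# interpolated from the column sums (their source row is inconsistently
# printed) and are therefore uncertain; all rows are renormalized to sum to 1.

default_item_probs <- function() {
  norm_rows <- function(spec) {
    spec$probs <- spec$probs / rowSums(spec$probs)
    spec
  }
  lapply(list(
    # bands are (lo, hi] on the raw scale used when drawing a value inside a
    # sampled category
    hours = list(
      probs = rbind(male   = c(11.4, 18.2, 52.3, 18.1),   # Q4 interpolated
                    female = c(43.4, 34.6, 17.6, 4.4)) / 100,
      bands = rbind(c(1, 20), c(20, 35), c(35, 41), c(41, 60))
    ),
    # income bands describe the equivalized (single-person-equivalent) scale
    income = list(
      probs = rbind(male   = c(20.7, 22.5, 28.4, 28.4),
                    female = c(32.8, 26.7, 25.2, 15.3)) / 100,
      bands = rbind(c(510, 1900), c(1900, 2399), c(2400, 2999), c(3000, 5446))
    ),
    education = list(
      probs = rbind(male   = c(29.9, 24.3, 45.8),
                    female = c(29.4, 30.9, 39.7)) / 100,
      levels = c("low", "intermediate", "high")
    ),
    caregiving = list(
      probs = rbind(male   = c(83.2, 13.4, 3.4),
                    female = c(62.3, 26.3, 11.4)) / 100,
      bands = rbind(c(0, 0), c(0.5, 7.5), c(8, 20))
    ),
    chores = list(
      probs = rbind(male   = c(42.4, 29.9, 15.8, 11.9),
                    female = c(5.9, 16.9, 35.3, 41.9)) / 100,
      bands = rbind(c(0, 24), c(24, 60), c(60, 120), c(120, 240))
    ),
    segregation = list(
      probs = rbind(male   = c(41.2, 27.1, 27.7, 4.0),
                    female = c(8.1, 11.0, 65.4, 15.4)) / 100,
      bands = rbind(c(0, 25), c(26, 50), c(51, 75), c(76, 100))
    )
  ), norm_rows)
}

# Probability of scoring "high" on each working condition, by gender-role
# group (masculine/feminine), plus the sum-score range and the cut value at
# which the within-cohort median concentrates.
default_wc_prevalence <- function() {
  list(
    probs = rbind(
      masculine = c(physical = 0.362, psychosocial = 0.443, cognitive = 0.454,
                    autonomy = 0.476, variation = 0.425, support = 0.389),
      feminine  = c(physical = 0.602, psychosocial = 0.438, cognitive = 0.227,
                    autonomy = 0.328, variation = 0.306, support = 0.352)
    ),
    range = rbind(physical = c(5, 20), psychosocial = c(2, 8),
                  cognitive = c(6, 24), autonomy = c(3, 12),
                  variation = c(1, 4), support = c(4, 16)),
    cut = c(physical = 12, psychosocial = 5, cognitive = 15,
            autonomy = 7, variation = 2, support = 10)
  )
}

default_outcome_coefs <- function() {
  list(
    intercept = 6.6,
    female = 0,
    feminine = 1.85,
    wc = c(physical = -0.48, psychosocial = -0.48, cognitive = 0.42,
           autonomy = -1.57, variation = -2.13, support = -1.33),
    age = 0
  )
}

#' Configuration for the synthetic older-worker cohort generator
#'
#' Defaults emulate a population-based sample of 313 Dutch older workers:
#' 43.5% female, age about N(58.9, 2.4), sex-specific category frequencies
#' for the six gender-role items, gender-specific prevalence of "high"
#' working conditions, and a right-skewed depressive-symptom score (CES-D,
#' 0-60) produced by censoring a latent normal at zero.
#'
#' @param n Number of persons (default 313).
#' @param p_female Probability of female sex (default 0.435).
#' @param age_mean,age_sd Age distribution in years (defaults 58.9 and 2.4).
#' @param p_partner Probability of living with a partner (default 0.8).
#' @param item_probs Per-sex category probability tables and raw-value bands
#'   for the six gender items; see `default_item_probs()` in the source for
#'   the structure. Every probability row must sum to 1.
#' @param wc_prevalence Per-gender-group probability of "high" for each of
#'   the six working conditions, plus sum-score ranges and cut values.
#' @param outcome_coefs Latent-scale coefficients: `intercept`, `female`
#'   (sex effect), `feminine` (gender effect), `wc` (named length-6 vector,
#'   effects of high working conditions), `age` (per year, centered), and
#'   optionally `interaction = list(wc = <condition>, coef = <number>)` for
#'   a gender-by-working-condition product term (default absent), used to
#'   study differential vulnerability under a known truth.
#' @param sigma Latent residual SD (> 0, default 5.6).
#' @param gender_cutoff Fixed gender-index cutoff used *inside the generator*
#'   to define the feminine group driving working conditions and outcome
#'   (default 7: masculine 0-7, feminine above).
#' @param missing_rate Marginal probability, in `[0, 1)`, that an imputable
#'   cell (gender items, working-condition scores, CES-D) is set missing
#'   under a missing-at-random rule driven by sex and age (default 0).
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A validated object of class `"cohort_config"`.
#' @export
cohort_config <- function(n = 313L, p_female = 0.435, age_mean = 58.9,
                          age_sd = 2.4, p_partner = 0.8,
                          item_probs = default_item_probs(),
                          wc_prevalence = default_wc_prevalence(),
                          outcome_coefs = default_outcome_coefs(),
                          sigma = 5.6, gender_cutoff = 7,
                          missing_rate = 0, seed = 1L) {
  cfg <- structure(list(
    n = as.integer(n), p_female = p_female, age_mean = age_mean,
    age_sd = age_sd, p_partner = p_partner, item_probs = item_probs,
    wc_prevalence = wc_prevalence, outcome_coefs = outcome_coefs,
    sigma = sigma, gender_cutoff = gender_cutoff,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n < 1L) stop("n must be at least 1")
  for (p in c("p_female", "p_partner")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$sigma <= 0) stop("sigma must be positive")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  for (item in names(cfg$item_probs)) {
    pr <- cfg$item_probs[[item]]$probs
    for (r in rownames(pr)) {
      s <- sum(pr[r, ])
      if (abs(s - 1) > 1e-12) {
        stop("probability row does not sum to 1: item '", item,
             "', row '", r, "' (sum = ", format(s, digits = 10), ")")
      }
      if (any(pr[r, ] < 0)) {
        stop("negative probability: item '", item, "', row '", r, "'")
      }
    }
  }
  wc <- cfg$wc_prevalence$probs
  if (any(wc < 0 | wc > 1)) stop("wc_prevalence probabilities must lie in [0, 1]")
  if (length(cfg$outcome_coefs$wc) != ncol(wc)) {
    stop("outcome_coefs$wc must have one coefficient per working condition")
  }
  invisible(cfg)
}

#' Read a generator configuration from YAML or JSON
#'
#' The file may specify any subset of [cohort_config()]'s scalar arguments
#' (`n`, `p_female`, `age_mean`, `age_sd`, `p_partner`, `sigma`,
#' `gender_cutoff`, `missing_rate`, `seed`) plus `outcome_coefs`; omitted
#' fields keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    # keep YAML-1.1 boolean-like keys (notably "n") as literal strings
    yaml::read_yaml(path, handlers = list("bool#yes" = function(x) x,
                                          "bool#no" = function(x) x))
  }
  allowed <- c("n", "p_female", "age_mean", "age_sd", "p_partner", "sigma",
               "gender_cutoff", "missing_rate", "seed", "outcome_coefs")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  if (!is.null(raw$outcome_coefs)) {
    oc <- default_outcome_coefs()
    for (nm in names(raw$outcome_coefs)) {
      oc[[nm]] <- if (nm == "interaction") raw$outcome_coefs[[nm]] else
        unlist(raw$outcome_coefs[[nm]])
    }
    if (is.null(names(oc$wc)) && length(oc$wc) == 6) names(oc$wc) <- wc_names()
    raw$outcome_coefs <- oc
  }
  do.call(cohort_config, raw)
}

wc_names <- function() {
  c("physical", "psychosocial", "cognitive", "autonomy", "variation", "support")
}
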