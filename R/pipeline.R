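# append gender index columns and dichotomized working-condition factors
prepare_analysis_data <- function(records, cutoff = "median") {
  idx <- build_gender_index(records, cutoff = cutoff)
  out <- cbind(records, idx)
  for (w in wc_names()) {
    out[[paste0("wc_", w, "_high")]] <- median_split(out[[paste0("wc_", w)]])
  }
  out
}

group_masks <- function(d) {
  list(male = d$sex == "male", female = d$sex == "female",
       masculine = d$gender_binary == "masculine",
       feminine = d$gender_binary == "feminine",
       total = rep(TRUE, nrow(d)))
}

# Table 1 analogue: category percentages of the coded gender items, "high"
# working-condition prevalence and CES-D mean/SD, by sex and by gender group
descriptives_table <- function(d) {
  gm <- group_masks(d)
  rows <- list(data.frame(statistic = "n", t(vapply(gm, sum, numeric(1)))))
  add <- function(label, values) {
    rows[[length(rows) + 1L]] <<- data.frame(statistic = label, t(values))
  }
  item_cols <- c(hours = "code_hours", income = "code_income",
                 segregation = "code_segregation", education = "code_education",
                 caregiving = "code_caregiving", chores = "code_chores")
  for (item in names(item_cols)) {
    codes <- d[[item_cols[item]]]
    for (lv in sort(unique(codes))) {
      add(paste0(item, "_code", lv),
          vapply(gm, function(mk) 100 * mean(codes[mk] == lv), numeric(1)))
    }
  }
  for (w in wc_names()) {
    hi <- d[[paste0("wc_", w, "_high")]] == "high"
    add(paste0("pct_high_", w),
        vapply(gm, function(mk) 100 * mean(hi[mk]), numeric(1)))
  }
  add("pct_female", vapply(gm, function(mk) 100 * mean(d$sex[mk] == "female"),
                           numeric(1)))
  add("pct_feminine",
      vapply(gm, function(mk) 100 * mean(d$gender_binary[mk] == "feminine"),
             numeric(1)))
  add("cesd_mean", vapply(gm, function(mk) mean(d$cesd[mk]), numeric(1)))
  add("cesd_sd", vapply(gm, function(mk) stats::sd(d$cesd[mk]), numeric(1)))
  do.call(rbind, rows)
}

# Table 2 analogue: per gender item, odds ratios of female sex by item
# category (reference = lowest code), plus the dichotomized index
gender_item_table <- function(d) {
  female <- as.integer(d$sex == "female")
  age <- d$age - mean(d$age)
  item_cols <- c(hours = "code_hours", income = "code_income",
                 segregation = "code_segregation", education = "code_education",
                 caregiving = "code_caregiving", chores = "code_chores")
  rows <- list()
  one_model <- function(item, x) {
    lv <- sort(unique(x))
    X <- cbind(1, vapply(lv[-1], function(l) as.numeric(x == l),
                         numeric(length(x))))
    colnames(X) <- c("(Intercept)", paste0(item, "_code", lv[-1]))
    fit <- tryCatch(fit_logistic(X, female), error = function(e) NULL)
    for (j in seq_along(lv[-1])) {
      nm <- paste0(item, "_code", lv[-1][j])
      rows[[length(rows) + 1L]] <<- data.frame(
        term = nm,
        log_or = if (is.null(fit)) NA_real_ else unname(fit$coefficients[nm]),
        se = if (is.null(fit)) NA_real_ else unname(fit$se[nm]))
    }
  }
  for (item in names(item_cols)) one_model(item, d[[item_cols[item]]])
  fem <- as.numeric(d$gender_binary == "feminine")
  fit <- fit_logistic(cbind(`(Intercept)` = 1, feminine = fem), female)
  rows[[length(rows) + 1L]] <- data.frame(
    term = "gender_index_feminine",
    log_or = unname(fit$coefficients["feminine"]),
    se = unname(fit$se["feminine"]))
  do.call(rbind, rows)
}

# Table 3 analogue rows for one completed dataset
moderation_table <- function(d) {
  rows <- list()
  for (grp in c("sex", "gender")) {
    for (w in wc_names()) {
      mr <- test_moderation(d, grp, w)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, wc = w,
        wc_main = mr$wc_main$estimate, wc_main_se = mr$wc_main$se,
        group_main = mr$group_main$estimate, group_main_se = mr$group_main$se,
        interaction = mr$interaction$estimate,
        interaction_se = mr$interaction$se, p = mr$interaction$p)
    }
  }
  do.call(rbind, rows)
}

# Table 4 analogue rows for one completed dataset
mediation_table <- function(d, n_boot, seed, scale) {
  rows <- list()
  i <- 0L
  for (grp in c("sex", "gender")) {
    for (w in wc_names()) {
      i <- i + 1L
      mr <- mediate(d, grp, w, n_boot = n_boot, seed = seed + i, scale = scale)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, wc = w,
        a = mr$a_path$estimate, a_se = mr$a_path$se,
        b = mr$b_path$estimate, b_se = mr$b_path$se,
        c = mr$c_path$estimate, c_se = mr$c_path$se,
        c_prime = mr$c_prime$estimate, c_prime_se = mr$c_prime$se,
        acme = mr$acme,
        acme_se = stats::sd(mr$acme_boot, na.rm = TRUE),
        acme_lower = mr$acme_ci[1], acme_upper = mr$acme_ci[2],
        n_failed = mr$n_failed)
    }
  }
  do.call(rbind, rows)
}

# Rubin-pool matching (est, se) column pairs across m copies of a table
pool_table <- function(tables, est_cols, se_cols, keep) {
  m <- length(tables)
  if (m == 1L) return(tables[[1]])
  out <- tables[[1]][keep]
  for (j in seq_along(est_cols)) {
    ec <- est_cols[j]; sc <- se_cols[j]
    ests <- lapply(tables, function(tb) {
      list(coef = tb[[ec]], se = tb[[sc]])
    })
    pooled <- pool_estimates(ests)
    out[[ec]] <- pooled$qbar
    out[[sc]] <- pooled$se
    out[[paste0(ec, "_lower")]] <- pooled$lower
    out[[paste0(ec, "_upper")]] <- pooled$upper
  }
  out
}

#' Run the full study replica end to end
#'
#' Simulate (or take) a cohort, impute missing values if present, construct
#' the gender index, dichotomize working conditions, and produce analogues of
#' the four study tables: descriptives, gender-item odds ratios for female
#' sex, moderation (differential vulnerability), and single-mediator
#' mediation (differential exposure). With `m >= 2` imputations, model tables
#' are pooled by Rubin's rules (for the indirect effect, the bootstrap
#' variance is plugged in as the within-imputation variance — a documented
#' approximation). Every random stage derives its seed from the configured
#' one, so a rerun is byte-identical.
#'
#' @param config A [cohort_config()]; its `seed` drives all stages.
#' @param records Optional cohort data frame (for example from
#'   [read_cohort()]); when supplied, generation is skipped.
#' @param n_boot Bootstrap resamples for each mediation model (default 500).
#' @param m Number of imputations when the cohort has missing values
#'   (default 30); ignored on complete data, where a single dataset is
#'   analysed and no pooling happens.
#' @param cutoff Gender-index cutoff (default within-sample median).
#' @param scale Indirect-effect scale passed to [mediate()].
#' @param out_dir If non-NULL, the report bundle (CSV tables + JSON
#'   manifest/log) is written there via [write_report_bundle()].
#' @return A list of class `"pipeline_result"`: `descriptives`,
#'   `gender_items`, `moderation`, `mediation` (data frames), `manifest`
#'   (config, seeds, counts, package version), `log` (per-stage notes).
#' @export
run_pipeline <- function(config = cohort_config(), records = NULL,
                         n_boot = 500L, m = 30L, cutoff = "median",
                         scale = c("latent", "expected"), out_dir = NULL) {
  scale <- match.arg(scale)
  log <- list()
  if (is.null(records)) {
    records <- generate_cohort(config)
    log$generated <- nrow(records)
  }

  has_missing <- any(vapply(imputable_columns(), function(col) {
    col %in% names(records) && anyNA(records[[col]])
  }, logical(1)))
  completed <- if (has_missing) {
    impute_cohorts(records, m = m, seed = config$seed + 1L)
  } else {
    list(records)
  }
  m_eff <- length(completed)
  log$imputations <- if (has_missing) m_eff else 0L
  if (has_missing && m_eff == 1L) {
    log$note <- "single imputation: no pooling variance"
  }

  analysed <- lapply(completed, prepare_analysis_data, cutoff = cutoff)

  desc_all <- lapply(analysed, descriptives_table)
  desc <- desc_all[[1]]
  if (m_eff > 1L) {
    num_cols <- setdiff(names(desc), "statistic")
    for (cc in num_cols) {
      desc[[cc]] <- rowMeans(vapply(desc_all, function(tb) tb[[cc]],
                                    numeric(nrow(desc))))
    }
  }

  t2 <- pool_table(lapply(analysed, gender_item_table),
                   est_cols = "log_or", se_cols = "se", keep = "term")
  if (m_eff == 1L) {
    t2$log_or_lower <- t2$log_or - stats::qnorm(0.975) * t2$se
    t2$log_or_upper <- t2$log_or + stats::qnorm(0.975) * t2$se
  }
  t2$or <- exp(t2$log_or)
  t2$or_lower <- exp(t2$log_or_lower)
  t2$or_upper <- exp(t2$log_or_upper)

  t3 <- pool_table(lapply(analysed, moderation_table),
                   est_cols = c("wc_main", "group_main", "interaction"),
                   se_cols = c("wc_main_se", "group_main_se", "interaction_se"),
                   keep = c("group", "wc"))
  if (m_eff == 1L) {
    z <- stats::qnorm(0.975)
    for (ec in c("wc_main", "group_main", "interaction")) {
      t3[[paste0(ec, "_lower")]] <- t3[[ec]] - z * t3[[paste0(ec, "_se")]]
      t3[[paste0(ec, "_upper")]] <- t3[[ec]] + z * t3[[paste0(ec, "_se")]]
    }
  } else {
    t3$p <- 2 * stats::pnorm(-abs(t3$interaction / t3$interaction_se))
  }

  t4_all <- lapply(seq_along(analysed), function(i) {
    mediation_table(analysed[[i]], n_boot = n_boot,
                    seed = config$seed + 100L * i, scale = scale)
  })
  t4 <- pool_table(t4_all,
                   est_cols = c("a", "b", "c", "c_prime", "acme"),
                   se_cols = c("a_se", "b_se", "c_se", "c_prime_se", "acme_se"),
                   keep = c("group", "wc"))
  if (m_eff == 1L) {
    z <- stats::qnorm(0.975)
    for (ec in c("a", "b", "c", "c_prime")) {
      t4[[paste0(ec, "_lower")]] <- t4[[ec]] - z * t4[[paste0(ec, "_se")]]
      t4[[paste0(ec, "_upper")]] <- t4[[ec]] + z * t4[[paste0(ec, "_se")]]
    }
    t4$acme_lower <- t4_all[[1]]$acme_lower
    t4$acme_upper <- t4_all[[1]]$acme_upper
  }
  log$mediation_failed_resamples <- sum(vapply(t4_all, function(tb)
    sum(tb$n_failed), numeric(1)))
  log$multiplicity_note <- paste(
    "moderation/mediation p-values are unadjusted;",
    "the moderation table spans 12 interaction tests")

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "genderwork",
    version = as.character(utils::packageVersion("genderwork")),
    config = unclass(config),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = config$seed, n_boot = n_boot, m = m_eff,
    cutoff = cutoff, scale = scale
  )
  unlink(tmp)

  res <- structure(list(descriptives = desc, gender_items = t2,
                        moderation = t3, mediation = t4,
                        manifest = manifest, log = log),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

#' Write a pipeline report bundle to disk
#'
#' Emits `table1_descriptives.csv`, `table2_gender_items.csv`,
#' `table3_moderation.csv`, `table4_mediation.csv`, `manifest.json` and
#' `log.json` into `dir`. The files contain no timestamps, so a rerun with
#' the same configuration is byte-identical.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$descriptives,
                   file.path(dir, "table1_descriptives.csv"), row.names = FALSE)
  utils::write.csv(result$gender_items,
                   file.path(dir, "table2_gender_items.csv"), row.names = FALSE)
  utils::write.csv(result$moderation,
                   file.path(dir, "table3_moderation.csv"), row.names = FALSE)
  utils::write.csv(result$mediation,
                   file.path(dir, "table4_mediation.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(result$log, file.path(dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Study-replica pipeline result\n")
  cat("  cohort n:", x$descriptives[x$descriptives$statistic == "n", "total"],
      "  imputations:", x$manifest$m, "  n_boot:", x$manifest$n_boot, "\n")
  cm <- x$descriptives[x$descriptives$statistic == "cesd_mean", ]
  cat(sprintf("  CES-D mean: male %.2f, female %.2f, masculine %.2f, feminine %.2f\n",
              cm$male, cm$female, cm$masculine, cm$feminine))
  sig <- x$mediation[x$mediation$acme_lower > 0 | x$mediation$acme_upper < 0, ]
  cat("  indirect effects with CI excluding 0:",
      if (nrow(sig)) paste(sig$group, sig$wc, sep = ":", collapse = ", ")
      else "none", "\n")
  invisible(x)
}
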