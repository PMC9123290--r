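# shared preparation: binary exposure (female/feminine = 1), binary mediator
# ("high" working condition), centered age, complete CES-D
prepare_paths <- function(records, group, wc, cutoff = "median") {
  group <- match.arg(group, c("sex", "gender"))
  if (anyNA(records$cesd)) stop("cesd has missing values; impute first")
  t <- if (group == "sex") {
    as.integer(records$sex == "female")
  } else {
    gb <- if ("gender_binary" %in% names(records)) {
      records$gender_binary
    } else {
      build_gender_index(records, cutoff = cutoff)$gender_binary
    }
    as.integer(gb == "feminine")
  }
  if (length(unique(t)) < 2L) {
    stop("group '", group, "' is constant in these records")
  }
  col <- paste0("wc_", wc)
  if (!col %in% names(records)) stop("unknown working condition: ", wc)
  m <- as.integer(median_split(records[[col]]) == "high")
  age_c <- records$age - mean(records$age)
  list(t = t, m = m, age = age_c, y = records$cesd,
       group = group, wc = wc)
}

#' Test differential vulnerability: sex/gender x working-condition moderation
#'
#' Fits a tobit model of CES-D on a dichotomized working condition, the
#' sex or gender group, their interaction, and age:
#' `cesd ~ wc_high + group + wc_high:group + age`. Reference groups are
#' male/masculine and low exposure. A Wald z test on the interaction
#' coefficient asks whether the working condition's association with
#' depressive symptoms differs between groups.
#'
#' @param records Cohort data frame with complete `cesd`; `gender_binary` is
#'   derived on the fly if absent.
#' @param group `"sex"` or `"gender"`.
#' @param wc One of `"physical"`, `"psychosocial"`, `"cognitive"`,
#'   `"autonomy"`, `"variation"`, `"support"`.
#' @param cutoff Gender-index cutoff passed to [build_gender_index()] when
#'   `gender_binary` is absent.
#' @return An object of class `"moderation_result"` with components
#'   `wc_main`, `group_main`, `interaction` (each estimate, se, 95% CI; the
#'   interaction also a Wald p), `group_label`, `wc_label`, and `fit`.
#' @export
test_moderation <- function(records, group = c("sex", "gender"), wc,
                            cutoff = "median") {
  d <- prepare_paths(records, group, wc, cutoff)
  tab <- table(d$t, d$m)
  if (any(tab == 0) || any(dim(tab) < 2L)) {
    empty <- which(tab == 0, arr.ind = TRUE)
    lab <- if (length(empty)) {
      paste0("group=", rownames(tab)[empty[1, 1]], ", wc=",
             colnames(tab)[empty[1, 2]])
    } else "a degenerate margin"
    stop("empty cell in group x working-condition table: ", lab)
  }
  X <- cbind(`(Intercept)` = 1, wc_high = d$m, group = d$t,
             interaction = d$m * d$t, age = d$age)
  fit <- fit_tobit(X, d$y)
  ci <- confint(fit)
  z <- fit$coefficients["interaction"] / fit$se["interaction"]
  term <- function(nm) {
    list(estimate = unname(fit$coefficients[nm]), se = unname(fit$se[nm]),
         ci = unname(ci[nm, ]))
  }
  structure(list(
    wc_main = term("wc_high"), group_main = term("group"),
    interaction = c(term("interaction"),
                    list(p = unname(2 * stats::pnorm(-abs(z))))),
    group_label = d$group, wc_label = d$wc, fit = fit
  ), class = "moderation_result")
}

#' @export
print.moderation_result <- function(x, ...) {
  fmt <- function(tm) sprintf("%.3f (%.3f; %.3f)", tm$estimate, tm$ci[1], tm$ci[2])
  cat("Moderation of ", x$wc_label, " by ", x$group_label, "\n",
      "  working condition: ", fmt(x$wc_main), "\n",
      "  ", x$group_label, ": ", fmt(x$group_main), "\n",
      "  interaction: ", fmt(x$interaction),
      ", p = ", format.pval(x$interaction$p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Average causal mediation effect for a binary mediator
#'
#' Combines a fitted exposure-to-mediator logistic model (`mediator ~
#' exposure + age`) and a mediator-plus-exposure outcome tobit (`cesd ~
#' mediator + exposure + age`) into the indirect effect. On the latent
#' (linear-predictor) scale the product form is exact:
#' \deqn{ACME = \beta_M \cdot \frac{1}{n}\sum_i
#'   [\hat p_i(M=1 \mid T=1) - \hat p_i(M=1 \mid T=0)]}
#' with each person's own age and the exposure counterfactually switched. On
#' the `"expected"` scale the same mediator-probability contrast is pushed
#' through [tobit_expected()], i.e. the censored-outcome mean, averaged over
#' the two exposure levels.
#'
#' @param a_fit A `logistic_fit` with coefficients (intercept, exposure, age).
#' @param b_fit A `tobit_fit` with coefficients (intercept, mediator,
#'   exposure, age).
#' @param age Centered age vector on the scale both fits used.
#' @param scale `"latent"` (default) or `"expected"`.
#' @return The indirect effect (a single number, CES-D points).
#' @export
acme_binary_mediator <- function(a_fit, b_fit, age, scale = c("latent", "expected")) {
  scale <- match.arg(scale)
  stopifnot(inherits(a_fit, "logistic_fit"), inherits(b_fit, "tobit_fit"))
  if (length(a_fit$coefficients) != 3L || length(b_fit$coefficients) != 4L) {
    stop("a_fit must be (intercept, exposure, age); ",
         "b_fit must be (intercept, mediator, exposure, age)")
  }
  n <- length(age)
  p1 <- predict(a_fit, cbind(1, 1, age))
  p0 <- predict(a_fit, cbind(1, 0, age))
  if (scale == "latent") {
    return(unname(b_fit$coefficients[2L]) * mean(p1 - p0))
  }
  acme_t <- vapply(c(0, 1), function(t) {
    e1 <- tobit_expected(b_fit, cbind(1, 1, t, age))
    e0 <- tobit_expected(b_fit, cbind(1, 0, t, age))
    mean((e1 - e0) * (p1 - p0))
  }, numeric(1))
  mean(acme_t)
}

# one pass of the three path models; se only when needed
fit_paths <- function(d, se = TRUE) {
  if (length(unique(d$m)) < 2L) stop("mediator constant in resample")
  a  <- fit_logistic(cbind(1, exposure = d$t, age = d$age), d$m)
  bc <- fit_tobit(cbind(1, mediator = d$m, exposure = d$t, age = d$age),
                  d$y, se = se)
  cc <- fit_tobit(cbind(1, exposure = d$t, age = d$age), d$y, se = se)
  list(a = a, bc = bc, cc = cc)
}

#' Single-mediator causal mediation of sex/gender on depressive symptoms
#'
#' Tests differential exposure: does a working condition transmit part of the
#' sex or gender difference in CES-D scores? Fits, on the analysis sample,
#' \itemize{
#'   \item a path: logistic `mediator ~ exposure + age`;
#'   \item b and c' paths: tobit `cesd ~ mediator + exposure + age`;
#'   \item c path: tobit `cesd ~ exposure + age`;
#' }
#' and the indirect effect via [acme_binary_mediator()]. The 95% interval for
#' the indirect effect is a percentile interval over `n_boot` nonparametric
#' resamples of persons (dichotomizations are taken as fixed person-level
#' values). Resamples where any path model fails are dropped and counted;
#' more than 10% failures is an error.
#'
#' @inheritParams test_moderation
#' @param mediator Working-condition name (see [test_moderation()]'s `wc`).
#' @param n_boot Number of bootstrap resamples (default 500).
#' @param seed Integer seed for the resampling.
#' @param scale Indirect-effect scale, `"latent"` or `"expected"`.
#' @return An object of class `"mediation_result"`: `a_path`, `b_path`,
#'   `c_path`, `c_prime` (estimate, se, 95% Wald CI each), `acme`,
#'   `acme_ci` (bootstrap percentile), `acme_boot` (the resample values),
#'   `n_boot`, `n_failed`, `scale`, `seed`, labels.
#' @export
mediate <- function(records, exposure = c("sex", "gender"), mediator,
                    n_boot = 500L, seed = 1L,
                    scale = c("latent", "expected"), cutoff = "median") {
  scale <- match.arg(scale)
  d <- prepare_paths(records, exposure, mediator, cutoff)
  fits <- fit_paths(d, se = TRUE)
  acme <- acme_binary_mediator(fits$a, fits$bc, d$age, scale)

  n <- length(d$y)
  if (n_boot < 1L) stop("n_boot must be at least 1")
  set.seed(seed)
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    db <- list(t = d$t[idx], m = d$m[idx], age = d$age[idx], y = d$y[idx])
    boot[b] <- tryCatch({
      fb <- suppressWarnings(fit_paths(db, se = FALSE))
      acme_binary_mediator(fb$a, fb$bc, db$age, scale)
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(boot))
  if (n_failed > 0.10 * n_boot) {
    stop(n_failed, " of ", n_boot, " bootstrap resamples failed to fit")
  }
  ok <- boot[!is.na(boot)]
  acme_ci <- if (length(ok) == 1L) rep(ok, 2L) else
    unname(stats::quantile(ok, c(0.025, 0.975)))

  z <- stats::qnorm(0.975)
  term <- function(fit, nm) {
    est <- unname(fit$coefficients[nm])
    se <- unname(fit$se[nm])
    list(estimate = est, se = se, ci = c(est - z * se, est + z * se))
  }
  structure(list(
    a_path = term(fits$a, "exposure"),
    b_path = term(fits$bc, "mediator"),
    c_path = term(fits$cc, "exposure"),
    c_prime = term(fits$bc, "exposure"),
    acme = acme, acme_ci = acme_ci, acme_boot = boot,
    n_boot = as.integer(n_boot), n_failed = n_failed,
    scale = scale, seed = as.integer(seed),
    exposure_label = d$group, mediator_label = d$wc, n = n
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(tm) sprintf("%.3f (%.3f; %.3f)", tm$estimate, tm$ci[1], tm$ci[2])
  cat("Single-mediator model: ", x$exposure_label, " -> ", x$mediator_label,
      " -> CES-D (n = ", x$n, ")\n",
      "  a path (logistic): ", fmt(x$a_path), "\n",
      "  b path (tobit):    ", fmt(x$b_path), "\n",
      "  c path (total):    ", fmt(x$c_path), "\n",
      "  c' path (direct):  ", fmt(x$c_prime), "\n",
      "  indirect effect (", x$scale, " scale): ",
      sprintf("%.3f (%.3f; %.3f)", x$acme, x$acme_ci[1], x$acme_ci[2]),
      "  [", x$n_boot, " bootstrap resamples, ", x$n_failed, " failed]\n",
      sep = "")
  invisible(x)
}
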