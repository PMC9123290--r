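#' Fit a logistic regression for a binary target
#'
#' Thin wrapper around [stats::glm()] with a binomial family (iteratively
#' reweighted least squares), used for the exposure-to-mediator ("a") paths
#' and for regressions of gender items on sex. Odds ratios are `exp(coef)`
#' with Wald 95% intervals.
#'
#' @param X Design matrix including the intercept column.
#' @param b Binary outcome: logical, 0/1 numeric, or two-level factor.
#' @return An object of class `"logistic_fit"`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `converged`, `n`, plus `or` and `or_ci` (odds ratios with 95%
#'   Wald bounds).
#' @export
fit_logistic <- function(X, b) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("design matrix contains non-finite entries")
  if (is.factor(b)) b <- as.integer(b) - 1L
  b <- as.numeric(b)
  if (anyNA(b) || !all(b %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (length(unique(b)) < 2L) stop("outcome has a single class; cannot fit")

  fit <- suppressWarnings(
    stats::glm.fit(X, b, family = stats::binomial(), intercept = FALSE)
  )
  co <- fit$coefficients
  if (anyNA(co)) stop("design matrix is rank deficient")
  mu <- fit$fitted.values
  # complete/quasi-complete separation: fitted probabilities pinned at 0/1
  if (!fit$converged || any(abs(co) > 30) ||
      all(mu[b == 1] > 1 - 1e-8) && all(mu[b == 0] < 1e-8)) {
    stop("separation detected: logistic MLE does not exist; ",
         "consider a penalized fit")
  }
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  vc <- solve(info)
  dimnames(vc) <- list(names(co), names(co))
  se <- sqrt(diag(vc))
  z <- stats::qnorm(0.975)

  structure(list(
    coefficients = co, se = se, vcov = vc,
    loglik = sum(stats::dbinom(b, 1, mu, log = TRUE)),
    converged = fit$converged, n = length(b),
    or = exp(co),
    or_ci = cbind(lower = exp(co - z * se), upper = exp(co + z * se))
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression, n = ", x$n,
      ", logLik = ", format(x$loglik, digits = 6), "\n", sep = "")
  print(cbind(Estimate = x$coefficients, `Std. Error` = x$se,
              OR = x$or, x$or_ci), ...)
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' Predicted probabilities from a logistic fit
#'
#' @param object A `logistic_fit`.
#' @param X New design matrix matching the fit's coefficients.
#' @param ... Unused.
#' @return Vector of probabilities.
#' @export
predict.logistic_fit <- function(object, X, ...) {
  X <- matrix(as.numeric(X), ncol = length(object$coefficients))
  stats::plogis(drop(X %*% object$coefficients))
}
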