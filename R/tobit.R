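#' Tobit log-likelihood for a left-censored-at-zero outcome
#'
#' The outcome is modelled as a latent normal `y* = X b + e`, `e ~ N(0,
#' sigma^2)`, observed as `y = max(0, y*)`. Uncensored rows contribute the
#' normal log-density, censored rows (`y = 0`) the log-probability mass below
#' zero:
#' \deqn{\ell = \sum_{y_i>0} \log\phi((y_i - x_i b)/\sigma) - \log\sigma
#'       + \sum_{y_i=0} \log\Phi(-x_i b / \sigma)}
#'
#' @param beta Coefficient vector, length `ncol(X)`.
#' @param sigma Residual scale, > 0.
#' @param X Design matrix (include an intercept column if wanted).
#' @param y Non-negative outcome vector.
#' @return The log-likelihood (a single number).
#' @export
tobit_loglik <- function(beta, sigma, X, y) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("design matrix contains non-finite entries")
  if (any(!is.finite(y)) || any(y < 0)) stop("y must be finite and non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  mu <- drop(X %*% beta)
  cens <- y == 0
  ll <- numeric(length(y))
  ll[!cens] <- stats::dnorm(y[!cens], mu[!cens], sigma, log = TRUE)
  ll[cens]  <- stats::pnorm(-mu[cens] / sigma, log.p = TRUE)
  sum(ll)
}

# gradient of the tobit log-likelihood in theta = (beta, log sigma)
tobit_grad <- function(theta, X, y) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  sigma <- exp(theta[p + 1L])
  mu <- drop(X %*% beta)
  cens <- y == 0
  g_beta <- numeric(p)
  g_logs <- 0
  if (any(!cens)) {
    r <- (y[!cens] - mu[!cens]) / sigma
    g_beta <- g_beta + drop(crossprod(X[!cens, , drop = FALSE], r / sigma))
    g_logs <- g_logs + sum(r^2 - 1)
  }
  if (any(cens)) {
    z <- -mu[cens] / sigma
    # inverse Mills ratio phi(z)/Phi(z), computed on the log scale for stability
    lambda <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    g_beta <- g_beta - drop(crossprod(X[cens, , drop = FALSE], lambda / sigma))
    g_logs <- g_logs + sum(lambda * (mu[cens] / sigma))
  }
  c(g_beta, g_logs)
}

# finite-difference Hessian of the log-likelihood from the analytic gradient
tobit_hessian_fd <- function(theta, X, y) {
  k <- length(theta)
  H <- matrix(0, k, k)
  h <- 1e-5 * pmax(1, abs(theta))
  for (j in seq_len(k)) {
    up <- dn <- theta
    up[j] <- up[j] + h[j]
    dn[j] <- dn[j] - h[j]
    H[, j] <- (tobit_grad(up, X, y) - tobit_grad(dn, X, y)) / (2 * h[j])
  }
  (H + t(H)) / 2
}

#' Fit a tobit (left-censored normal) regression by maximum likelihood
#'
#' Maximizes [tobit_loglik()] over `(beta, log sigma)` by BFGS with an
#' analytic gradient, started from OLS on the uncensored subset, followed by
#' Newton polishing until the gradient infinity-norm falls below `gtol`.
#' Standard errors come from the inverse observed information; the standard
#' error of `sigma` is obtained from that of `log sigma` by the delta method.
#'
#' @param X Design matrix; supply the intercept column yourself (see
#'   [stats::model.matrix()]).
#' @param y Outcome vector, left-censored at `left_limit`.
#' @param left_limit Censoring point (default 0); internally the outcome is
#'   shifted so the limit is zero.
#' @param se Compute the observed-information covariance and standard errors
#'   (skip for speed inside bootstrap loops).
#' @param gtol Gradient infinity-norm declared converged.
#' @param max_iter Maximum Newton polishing iterations after BFGS.
#' @return An object of class `"tobit_fit"`: `coefficients`, `sigma`, `se`
#'   (per coefficient), `se_sigma`, `vcov` (of `(beta, log sigma)`),
#'   `loglik`, `loglik_start`, `n`, `n_censored`, `converged`, `gradient`.
#' @export
fit_tobit <- function(X, y, left_limit = 0, se = TRUE, gtol = 1e-6,
                      max_iter = 50L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(!is.finite(X))) stop("design matrix contains non-finite entries")
  y <- as.numeric(y) - left_limit
  if (any(!is.finite(y))) stop("y contains non-finite entries")
  y[y < 0] <- 0
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  unc <- y > 0
  if (!any(unc)) stop("no uncensored data: every observation is at the limit")

  # start from OLS on the uncensored subset
  ols <- stats::lm.fit(X[unc, , drop = FALSE], y[unc])
  beta0 <- ols$coefficients
  beta0[is.na(beta0)] <- 0
  sd0 <- stats::sd(ols$residuals)
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- max(stats::sd(y[unc]), 1e-3)
  theta <- c(beta0, log(sd0))

  negll <- function(th) {
    -tobit_loglik(th[seq_len(p)], exp(th[p + 1L]), X, y)
  }
  neggr <- function(th) -tobit_grad(th, X, y)
  ll_start <- -negll(theta)

  opt <- stats::optim(theta, negll, neggr, method = "BFGS",
                      control = list(maxit = 300L, reltol = 1e-14))
  theta <- opt$par
  g <- tobit_grad(theta, X, y)
  ll <- -opt$value

  # Newton polishing with backtracking line search
  iter <- 0L
  while (max(abs(g)) > gtol && iter < max_iter) {
    H <- tobit_hessian_fd(theta, X, y)
    # H is the Hessian of the log-likelihood: ascend along -solve(H, g);
    # fall back to a plain gradient step when H is singular
    step <- tryCatch(-solve(H, g), error = function(e) g / max(abs(g)))
    alpha <- 1
    repeat {
      cand <- theta + alpha * step
      ll_cand <- -negll(cand)
      if (is.finite(ll_cand) && ll_cand >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8) break
    theta <- theta + alpha * step
    ll <- -negll(theta)
    g <- tobit_grad(theta, X, y)
    iter <- iter + 1L
  }

  converged <- max(abs(g)) < gtol
  if (!converged) {
    warning("tobit fit did not reach gradient tolerance (max |grad| = ",
            format(max(abs(g)), digits = 3), ")")
  }
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)
  sigma <- unname(exp(theta[p + 1L]))

  vc <- se_beta <- se_sigma <- NULL
  if (se) {
    H <- tobit_hessian_fd(theta, X, y)
    vc <- tryCatch(solve(-H), error = function(e) NULL)
    if (!is.null(vc)) {
      dimnames(vc) <- list(c(names(beta), "log_sigma"),
                           c(names(beta), "log_sigma"))
      dg <- diag(vc)
      if (all(dg > 0)) {
        se_beta <- sqrt(dg[seq_len(p)])
        se_sigma <- sigma * sqrt(dg[p + 1L])  # delta method
      }
    }
  }

  structure(list(
    coefficients = beta, sigma = sigma, se = se_beta, se_sigma = se_sigma,
    vcov = vc, loglik = ll, loglik_start = ll_start, n = n,
    n_censored = sum(!unc), converged = converged, gradient = g,
    left_limit = left_limit
  ), class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat("Tobit regression (left-censored at ", x$left_limit, ")\n", sep = "")
  cat("n = ", x$n, ", censored = ", x$n_censored,
      ", logLik = ", format(x$loglik, digits = 6), "\n", sep = "")
  tab <- cbind(Estimate = x$coefficients,
               `Std. Error` = if (is.null(x$se)) NA_real_ else x$se)
  print(tab, ...)
  cat("sigma = ", format(x$sigma, digits = 6),
      if (!is.null(x$se_sigma)) paste0(" (se ", format(x$se_sigma, digits = 4), ")"),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.tobit_fit <- function(object, ...) object$coefficients

#' @export
logLik.tobit_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1L,
            class = "logLik")
}

#' Wald confidence intervals for a tobit fit
#'
#' @param object A `tobit_fit`.
#' @param parm Coefficients to include (default all).
#' @param level Confidence level.
#' @param ... Unused.
#' @return Matrix of lower/upper bounds.
#' @export
confint.tobit_fit <- function(object, parm = NULL, level = 0.95, ...) {
  if (is.null(object$se)) stop("fit was computed without standard errors")
  est <- object$coefficients
  if (is.null(parm)) parm <- names(est)
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lower = est[parm] - z * object$se[parm],
        upper = est[parm] + z * object$se[parm])
}

#' Expected observed outcome under a tobit fit
#'
#' For a latent normal censored below at zero, the mean of the *observed*
#' outcome is `E[y | x] = Phi(z) x b + sigma phi(z)` with `z = x b / sigma`;
#' it is always non-negative and approaches `x b` when censoring vanishes.
#'
#' @param fit A converged `tobit_fit`.
#' @param X Design matrix (or single row) matching the fit's coefficients.
#' @return Numeric vector of expected outcomes.
#' @export
tobit_expected <- function(fit, X) {
  stopifnot(inherits(fit, "tobit_fit"))
  if (!fit$converged) stop("tobit fit did not converge")
  X <- matrix(as.numeric(X), ncol = length(fit$coefficients))
  mu <- drop(X %*% fit$coefficients)
  z <- mu / fit$sigma
  stats::pnorm(z) * mu + fit$sigma * stats::dnorm(z)
}
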