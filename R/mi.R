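# numeric coding of the analysis columns used as imputation predictors
mi_numeric_frame <- function(records) {
  num <- list(
    female = as.numeric(records$sex == "female"),
    age = records$age,
    has_partner = as.numeric(records$has_partner)
  )
  for (col in imputable_columns()) {
    num[[col]] <- if (col == "education") {
      as.numeric(factor(records[[col]], levels = c("low", "intermediate", "high")))
    } else {
      as.numeric(records[[col]])
    }
  }
  do.call(cbind, num)
}

# one predictive-mean-matching draw: linear fit of the target on all other
# columns over originally-observed rows, k-nearest-donor sampling for the rest
pmm_draw <- function(num, target, miss, k) {
  obs <- !miss
  X <- cbind(1, num[, setdiff(colnames(num), target), drop = FALSE])
  y <- num[, target]
  fit <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  yhat <- drop(X %*% beta)
  donors <- which(obs)
  for (i in which(miss)) {
    d <- abs(yhat[donors] - yhat[i])
    near <- donors[order(d)[seq_len(min(k, length(donors)))]]
    num[i, target] <- y[sample(near, 1L)]
  }
  num[, target]
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing values in the gender items, working-condition scores and
#' CES-D by chained equations: each incomplete column is regressed in turn on
#' all other analysis variables (sex, age, partner status and the remaining
#' items) and missing cells receive the observed value of a donor sampled
#' from the `k` candidates with the closest predicted mean. Predictive mean
#' matching is used for every variable type, so imputed values are always
#' observed values of the right type (integer scores stay integer, education
#' stays one of its three levels). Observed cells are never altered.
#'
#' @param records Cohort data frame, possibly with missing values in the
#'   imputable columns only.
#' @param m Number of completed datasets (default 30). `m = 1` warns that
#'   between-imputation variance cannot be estimated.
#' @param cycles Chained-equation cycles per dataset (default 10).
#' @param k Donor pool size (default 5).
#' @param seed Integer seed.
#' @return A list of `m` completed cohort data frames.
#' @export
impute_cohorts <- function(records, m = 30L, cycles = 10L, k = 5L, seed = 1L) {
  if (m < 1L) stop("m must be at least 1")
  if (m == 1L) warning("m = 1: pooling variance will be undefined")
  fixed <- c("female", "age", "has_partner")
  for (col in fixed_source_columns()) {
    if (anyNA(records[[col]])) stop("column '", col, "' must be complete")
  }
  targets <- intersect(imputable_columns(), names(records))
  miss <- lapply(targets, function(col) is.na(records[[col]]))
  names(miss) <- targets
  all_miss <- names(Filter(all, miss))
  if (length(all_miss)) {
    stop("column(s) 100% missing, cannot impute: ",
         paste(all_miss, collapse = ", "))
  }
  targets <- names(Filter(any, miss))
  if (!length(targets)) {
    return(replicate(m, records, simplify = FALSE))
  }

  set.seed(seed)
  edu_levels <- c("low", "intermediate", "high")
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    num <- mi_numeric_frame(records)
    # initial fill: random draws from each column's observed values
    for (col in targets) {
      obs_vals <- num[!miss[[col]], col]
      num[miss[[col]], col] <- sample(obs_vals, sum(miss[[col]]), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (col in targets) {
        num[, col] <- pmm_draw(num, col, miss[[col]], k)
      }
    }
    completed <- records
    for (col in targets) {
      filled <- num[, col]
      completed[[col]] <- if (col == "education") {
        factor(edu_levels[filled], levels = edu_levels)
      } else if (is.integer(records[[col]])) {
        as.integer(filled)
      } else {
        filled
      }
    }
    out[[imp]] <- completed
  }
  out
}

fixed_source_columns <- function() c("sex", "age", "has_partner")

#' Pool estimates across multiple imputations by Rubin's rules
#'
#' For `m` per-imputation estimates `q_j` with standard errors `se_j`:
#' pooled estimate `qbar = mean(q_j)`, within-imputation variance
#' `W = mean(se_j^2)`, between-imputation variance `B = var(q_j)`, total
#' variance `T = W + (1 + 1/m) B`, degrees of freedom
#' `df = (m - 1) (1 + W / ((1 + 1/m) B))^2`, and a 95% interval from the t
#' distribution on `df` (normal when `B = 0`, where `df` is infinite).
#'
#' @param estimates List of length `m >= 2`; each element a list (or named
#'   vector) with `coef` and `se`, each a named numeric vector over the same
#'   coefficient labels.
#' @return A data frame of class `"pooled_estimate"`, one row per
#'   coefficient: `qbar`, `W`, `B`, `T`, `df`, `se` (`sqrt(T)`), `lower`,
#'   `upper`, `m`.
#' @export
pool_estimates <- function(estimates) {
  if (!length(estimates)) stop("no estimates to pool")
  m <- length(estimates)
  if (m == 1L) stop("pooling requires m >= 2 imputations")
  labs <- names(estimates[[1]]$coef)
  if (is.null(labs)) labs <- paste0("b", seq_along(estimates[[1]]$coef))
  p <- length(labs)
  qmat <- matrix(vapply(estimates, function(e) unname(e$coef), numeric(p)),
                 nrow = m, byrow = TRUE)
  smat <- matrix(vapply(estimates, function(e) unname(e$se), numeric(p)),
                 nrow = m, byrow = TRUE)
  if (anyNA(qmat) || anyNA(smat)) stop("estimates contain missing values")

  qbar <- colMeans(qmat)
  W <- colMeans(smat^2)
  B <- apply(qmat, 2, stats::var)
  Tv <- W + (1 + 1 / m) * B
  df <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tq <- ifelse(is.finite(df), stats::qt(0.975, df), stats::qnorm(0.975))
  out <- data.frame(
    term = labs, qbar = qbar, W = W, B = B, T = Tv, df = df,
    se = sqrt(Tv), lower = qbar - tq * sqrt(Tv), upper = qbar + tq * sqrt(Tv),
    m = m, row.names = NULL
  )
  class(out) <- c("pooled_estimate", "data.frame")
  out
}
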