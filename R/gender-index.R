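#' Equivalize household income for household size
#'
#' Household income is made comparable between one- and two-person households
#' by multiplying by 0.7 (the inverse of the square root of 2, the number of
#' household members) for respondents living with a partner.
#'
#' @param income_monthly Numeric vector of monthly household incomes (euros),
#'   non-negative.
#' @param has_partner Logical vector (recycled): does the respondent share the
#'   household with a partner?
#' @return Numeric vector of equivalized incomes.
#' @examples
#' equivalize_income(2000, TRUE)   # 1400
#' equivalize_income(2000, FALSE)  # 2000
#' @export
equivalize_income <- function(income_monthly, has_partner) {
  if (any(!is.finite(income_monthly)) || any(income_monthly < 0)) {
    stop("income_monthly must be finite and non-negative")
  }
  if (!is.logical(has_partner) || anyNA(has_partner)) {
    stop("has_partner must be TRUE/FALSE without missing values")
  }
  income_monthly * ifelse(rep_len(has_partner, length(income_monthly)), 0.7, 1)
}

#' Quartile codes for a continuous gender item
#'
#' Assigns each value a femininity code 0-3 from sample quartiles
#' (linear-interpolation, type-7 quantiles at 0.25/0.5/0.75). Band membership
#' uses half-open intervals `[q_k, q_{k+1})`, with the top band closed. With
#' `reversed = TRUE` the lowest band scores 3 (used for items where *less* of
#' the raw quantity, e.g. working hours or income, is the feminine direction).
#'
#' @param values Numeric vector with at least 4 distinct values.
#' @param reversed Reverse the coding direction?
#' @return Integer vector of codes in 0..3.
#' @export
quartile_codes <- function(values, reversed = FALSE) {
  if (anyNA(values)) stop("values contain missing entries")
  if (length(unique(values)) < 4L) {
    stop("degenerate quartiles: need at least 4 distinct values")
  }
  q <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  code <- findInterval(values, unique(q))
  # collapse duplicated quartile boundaries conservatively, then rescale 0..3
  if (length(unique(q)) < 3L) {
    stop("degenerate quartiles: quartile boundaries coincide")
  }
  code <- as.integer(code)
  if (reversed) code <- 3L - code
  code
}

#' Occupation-segregation code
#'
#' Codes the percentage of female workers in the respondent's sector into four
#' femininity bands: 0 for <= 25%, 1 for 26-50%, 2 for 51-75%, 3 for >= 76%.
#'
#' @param pct_female_sector Numeric vector in \[0, 100\].
#' @return Integer vector of codes in 0..3.
#' @export
code_segregation <- function(pct_female_sector) {
  if (anyNA(pct_female_sector) ||
      any(pct_female_sector < 0 | pct_female_sector > 100)) {
    stop("pct_female_sector must lie in [0, 100]")
  }
  ifelse(pct_female_sector <= 25, 0L,
         ifelse(pct_female_sector <= 50, 1L,
                ifelse(pct_female_sector <= 75, 2L, 3L)))
}

#' Education code
#'
#' ISCED-2011-based three-level education, reversed so that *lower* education
#' is the feminine direction: high -> 0, intermediate -> 1, low -> 2.
#'
#' @param level Character vector with values in `c("low", "intermediate", "high")`.
#' @return Integer vector of codes in 0..2.
#' @export
code_education <- function(level) {
  codes <- c(high = 0L, intermediate = 1L, low = 2L)
  if (anyNA(level) || !all(level %in% names(codes))) {
    bad <- setdiff(unique(level), names(codes))
    stop("unknown education level: ", paste(bad, collapse = ", "))
  }
  unname(codes[level])
}

#' Informal-caregiving code
#'
#' 0 for no informal care, 1 for under 8 hours per week, 2 for 8 or more
#' hours per week.
#'
#' @param hours Numeric vector of weekly caregiving hours, non-negative.
#' @return Integer vector of codes in 0..2.
#' @export
code_caregiving <- function(hours) {
  if (anyNA(hours) || any(hours < 0)) stop("caregiving hours must be non-negative")
  ifelse(hours == 0, 0L, ifelse(hours < 8, 1L, 2L))
}

#' Median split of working-condition sum scores
#'
#' Dichotomizes scores at the sample median (type-7). A score strictly above
#' the median is "high"; scores equal to the median go to "low" (the
#' documented tie rule).
#'
#' @param scores Numeric vector, length >= 2.
#' @return Factor with levels `c("low", "high")`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop("median split needs at least 2 values")
  if (anyNA(scores)) stop("scores contain missing entries")
  m <- stats::median(scores)
  factor(ifelse(scores > m, "high", "low"), levels = c("low", "high"))
}

#' Build the six-item labour-market gender index
#'
#' Scores each person on six gender-role items and sums them into a composite
#' femininity index:
#' \itemize{
#'   \item working hours per week: sample quartiles, reversed (fewer hours =
#'     more feminine), codes 0-3;
#'   \item equivalized monthly household income (see [equivalize_income()]):
#'     sample quartiles, reversed, codes 0-3;
#'   \item occupation segregation: fixed percentage bands, codes 0-3;
#'   \item education: high/intermediate/low -> 0/1/2;
#'   \item informal caregiving: none / <8 h / >= 8 h per week -> 0/1/2;
#'   \item household chores (minutes per day): sample quartiles, not
#'     reversed, codes 0-3.
#' }
#' The total therefore ranges 0-16. The index is dichotomized into
#' masculine/feminine at a cutoff: by default the within-sample median of the
#' totals (feminine if total > cutoff, ties masculine); pass `cutoff = 7` for
#' the fixed masculine 0-7 / feminine 8+ replication split.
#'
#' @param records Data frame with columns `hours_per_week`, `income_monthly`,
#'   `has_partner`, `pct_female_sector`, `education`,
#'   `caregiving_hours_per_week`, `chores_min_per_day`. No missing values
#'   (impute first).
#' @param cutoff Either `"median"` (default) or a single number; feminine
#'   means total strictly greater than the cutoff.
#' @param income_quartiles_after_equivalization Compute income quartiles on
#'   the equivalized scale (default) or on raw income.
#' @return Data frame with one row per record: the six item codes
#'   (`code_hours`, `code_income`, `code_segregation`, `code_education`,
#'   `code_caregiving`, `code_chores`), `gender_total`, `gender_binary`
#'   (factor masculine/feminine) and `cutoff_used`.
#' @export
build_gender_index <- function(records, cutoff = "median",
                               income_quartiles_after_equivalization = TRUE) {
  needed <- c("hours_per_week", "income_monthly", "has_partner",
              "pct_female_sector", "education", "caregiving_hours_per_week",
              "chores_min_per_day")
  miss_col <- setdiff(needed, names(records))
  if (length(miss_col)) {
    stop("records lack required columns: ", paste(miss_col, collapse = ", "))
  }
  for (col in needed) {
    if (anyNA(records[[col]])) {
      ids <- if ("id" %in% names(records)) {
        paste(records$id[is.na(records[[col]])], collapse = ", ")
      } else {
        paste(which(is.na(records[[col]])), collapse = ", ")
      }
      stop("missing raw item '", col, "' for record(s): ", ids)
    }
  }

  inc <- if (income_quartiles_after_equivalization) {
    equivalize_income(records$income_monthly, records$has_partner)
  } else {
    records$income_monthly
  }

  codes <- data.frame(
    code_hours       = quartile_codes(records$hours_per_week, reversed = TRUE),
    code_income      = quartile_codes(inc, reversed = TRUE),
    code_segregation = code_segregation(records$pct_female_sector),
    code_education   = code_education(as.character(records$education)),
    code_caregiving  = code_caregiving(records$caregiving_hours_per_week),
    code_chores      = quartile_codes(records$chores_min_per_day, reversed = FALSE)
  )
  total <- as.integer(rowSums(codes))

  cut_val <- if (identical(cutoff, "median")) stats::median(total) else {
    stopifnot(is.numeric(cutoff), length(cutoff) == 1L)
    cutoff
  }
  codes$gender_total  <- total
  codes$gender_binary <- factor(ifelse(total > cut_val, "feminine", "masculine"),
                                levels = c("masculine", "feminine"))
  codes$cutoff_used   <- cut_val
  codes
}
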