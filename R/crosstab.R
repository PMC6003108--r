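#' Chi-square test of a contingency table with standardized residuals
#'
#' Pearson chi-square test of independence (no continuity correction) with
#' the standardized residual (O - E)/sqrt(E) per cell; |residual| > 2 flags a
#' cell as notably over- or under-represented. Adjusted residuals
#' (additionally divided by sqrt((1-row prop)(1-col prop))) are available as
#' an option.
#'
#' @param tab an observed-count matrix or table (levels x levels).
#' @param residual_type `"standardized"` (default) or `"adjusted"`.
#' @param flag_threshold absolute residual above which a cell is flagged.
#' @return Object of class `crosstab_result`: `observed`, `expected`, `chi2`,
#'   `df`, `p`, `std_residuals`, `flags` (tidy tibble of flagged cells) and
#'   `warning` (non-NULL when any expected count < 1).
#' @examples
#' chisq_residuals(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
#' @export
chisq_residuals <- function(tab, residual_type = c("standardized", "adjusted"),
                            flag_threshold = 2) {
  residual_type <- match.arg(residual_type)
  tab <- as.matrix(tab)
  if (any(tab < 0) || nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need a non-negative matrix with at least 2 rows and 2 columns",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- if (residual_type == "standardized") ct$residuals else ct$stdres
  flags <- which(abs(res) > flag_threshold, arr.ind = TRUE)
  flag_tbl <- tibble::tibble(
    row = rownames(res)[flags[, 1]] %||% as.character(flags[, 1]),
    col = colnames(res)[flags[, 2]] %||% as.character(flags[, 2]),
    residual = res[flags],
    direction = ifelse(res[flags] > 0, "over-represented", "under-represented")
  )
  warn <- if (any(ct$expected < 1)) {
    "some expected counts < 1; chi-square approximation unreliable"
  } else {
    NULL
  }
  structure(
    list(observed = tab, expected = ct$expected,
         chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value), std_residuals = res,
         residual_type = residual_type, flags = flag_tbl, warning = warn),
    class = "crosstab_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-tabulate a cohort factor against BMI classes
#'
#' Builds the factor-by-BMI-class (codes 1--5) contingency table for gender,
#' age group or education and tests independence. Underweight subjects and,
#' for education, unknown-education subjects are excluded.
#'
#' @param cohort augmented cohort tibble.
#' @param factor one of `"gender"`, `"age_group"`, `"education"`.
#' @inheritParams chisq_residuals
#' @return A `crosstab_result` (see [chisq_residuals()]).
#' @export
crosstab_test <- function(cohort, factor = c("gender", "age_group", "education"),
                          residual_type = c("standardized", "adjusted"),
                          flag_threshold = 2) {
  factor <- match.arg(factor)
  if (!"bmi_class" %in% names(cohort)) cohort <- augment_cohort(cohort)
  keep <- !cohort$excluded
  if (factor == "education") keep <- keep & cohort$education != "unknown"
  f <- cohort[[if (factor == "age_group") "age_label" else factor]][keep]
  lv <- switch(factor,
               gender = genders,
               age_group = names(age_group_levels),
               education = setdiff(education_levels, "unknown"))
  f <- factor(f, levels = lv)
  cls <- factor(cohort$bmi_label[keep], levels = names(bmi_class_levels)[-1])
  tab <- table(f, cls, dnn = c(factor, "bmi_class"))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("crosstab: fewer than 2 non-empty levels for ", factor, call. = FALSE)
  }
  out <- chisq_residuals(tab, residual_type = residual_type,
                         flag_threshold = flag_threshold)
  out$factor <- factor
  out
}

#' @export
print.crosstab_result <- function(x, ...) {
  cat("<crosstab_result> chi2 =", format(x$chi2, digits = 4),
      " df =", x$df, " p =", format.pval(x$p, digits = 3), "\n")
  if (nrow(x$flags)) {
    cat("  flagged cells (|", x$residual_type, " residual| > 2):\n", sep = "")
    print(as.data.frame(x$flags))
  }
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}
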