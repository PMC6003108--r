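#' Bias and accuracy from group means
#'
#' The core method-comparison quantities, computed from the mean measured and
#' mean estimated RMR: mean bias (estimated minus measured; positive means
#' overestimation), absolute bias |mean measured - mean estimated|, and the
#' percentage accuracy in both directions (absolute bias x 100 divided by the
#' measured or the estimated mean). Deviations under 10% are conventionally
#' regarded as adequate.
#'
#' @param mean_measured,mean_estimated group means, kcal/day.
#' @return A one-row tibble: `mean_bias`, `abs_bias`, `accuracy_vs_m`,
#'   `accuracy_vs_e` (percent).
#' @examples
#' bias_accuracy(1591, 1979) # abbreviated Harris-Benedict scale of error
#' @export
bias_accuracy <- function(mean_measured, mean_estimated) {
  ab <- abs(mean_measured - mean_estimated)
  tibble::tibble(
    mean_bias = mean_estimated - mean_measured,
    abs_bias = ab,
    accuracy_vs_m = ab * 100 / mean_measured,
    accuracy_vs_e = ab * 100 / mean_estimated
  )
}

#' Summarise agreement between measured and estimated RMR
#'
#' Per-equation agreement statistics on paired subject-level values:
#' descriptives of the estimates, mean bias with a two-sided 95% t confidence
#' interval on the mean of individual biases, absolute bias, percentage
#' accuracy against both means, and the count of subjects whose individual
#' percentage deviation |RMRe - RMRm| x 100 / RMRm is at most 10%.
#'
#' @param rmr_measured,rmr_estimated paired per-subject kcal/day vectors,
#'   finite and positive, excluded subjects already removed.
#' @param conf confidence level for the bias CI (default 0.95).
#' @return One-row tibble with fields `n`, `min`, `max`, `mean`, `sd` (of the
#'   estimates), `mean_bias`, `bias_lo`, `bias_hi`, `abs_bias`,
#'   `accuracy_vs_m`, `accuracy_vs_e`, `n_within_10`.
#' @export
summarize_agreement <- function(rmr_measured, rmr_estimated, conf = 0.95) {
  if (length(rmr_measured) != length(rmr_estimated)) {
    stop("measured and estimated vectors must be paired (equal length)",
         call. = FALSE)
  }
  if (length(rmr_measured) < 3) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (any(!is.finite(rmr_measured)) || any(!is.finite(rmr_estimated)) ||
      any(rmr_measured <= 0) || any(rmr_estimated <= 0)) {
    stop("RMR values must be finite and positive", call. = FALSE)
  }
  n <- length(rmr_measured)
  d <- rmr_estimated - rmr_measured
  se <- stats::sd(d) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  pct_dev <- abs(d) * 100 / rmr_measured
  ba <- bias_accuracy(mean(rmr_measured), mean(rmr_estimated))
  tibble::tibble(
    n = n,
    min = min(rmr_estimated), max = max(rmr_estimated),
    mean = mean(rmr_estimated), sd = stats::sd(rmr_estimated),
    mean_bias = mean(d),
    bias_lo = mean(d) - tcrit * se,
    bias_hi = mean(d) + tcrit * se,
    abs_bias = ba$abs_bias,
    accuracy_vs_m = ba$accuracy_vs_m,
    accuracy_vs_e = ba$accuracy_vs_e,
    n_within_10 = sum(pct_dev <= 10)
  )
}

#' Per-equation agreement table
#'
#' One row of agreement statistics per equation, preceded by a descriptive
#' row for the measured RMR itself, in equation-category order. Underweight
#' (excluded) subjects and subjects without a measured RMR are dropped;
#' placeholder equations (all-`NA` prediction columns) are skipped.
#'
#' @param pred prediction matrix from [predict_all()].
#' @param cohort the (augmented) cohort the matrix was built from; must carry
#'   `rmr_kcal_day` and, if present, the `excluded` flag.
#' @return A tibble, one row per equation plus the leading `RMRm` row, with a
#'   `category` column; columns as in [summarize_agreement()].
#' @export
agreement_table <- function(pred, cohort) {
  stopifnot(nrow(pred) == nrow(cohort))
  if (!"excluded" %in% names(cohort)) cohort <- augment_cohort(cohort)
  keep <- !cohort$excluded & is.finite(cohort$rmr_kcal_day)
  m <- cohort$rmr_kcal_day[keep]
  specs <- attr(pred, "specs")
  eq_names <- setdiff(names(pred), "id")
  cats <- vapply(eq_names, function(nm) {
    if (!is.null(specs[[nm]])) specs[[nm]]$category else NA_integer_
  }, integer(1))
  eq_names <- eq_names[order(cats)]

  measured_row <- tibble::tibble(
    equation = "RMRm", category = NA_integer_, n = length(m),
    min = min(m), max = max(m), mean = mean(m), sd = stats::sd(m),
    mean_bias = NA_real_, bias_lo = NA_real_, bias_hi = NA_real_,
    abs_bias = NA_real_, accuracy_vs_m = NA_real_, accuracy_vs_e = NA_real_,
    n_within_10 = NA_integer_
  )
  rows <- lapply(eq_names, function(nm) {
    e <- pred[[nm]][keep]
    if (all(is.na(e))) return(NULL)
    s <- summarize_agreement(m, e)
    tibble::tibble(equation = nm, category = cats[[nm]], s)
  })
  dplyr::bind_rows(measured_row, rows)
}

#' Adequacy of a prediction equation
#'
#' An equation is deemed adequately accurate when its percentage deviation is
#' strictly below the threshold (default 10%) against both the measured-mean
#' and estimated-mean denominators.
#'
#' @param summary a row from [summarize_agreement()] or [agreement_table()].
#' @param threshold percent, default 10.
#' @return Logical.
#' @export
adequacy_flag <- function(summary, threshold = 10) {
  summary$accuracy_vs_m < threshold & summary$accuracy_vs_e < threshold
}
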