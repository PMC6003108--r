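#' Per-kilogram RMR means by BMI class
#'
#' Mean measured RMR per kg body weight (kcal/kg/day) in each BMI class 1--5,
#' with a two-sided 95% t confidence interval and the class count.
#' Underweight subjects are excluded; empty classes are omitted with a
#' warning.
#'
#' @param cohort augmented cohort with `rmr_kcal_day` and `weight_kg`.
#' @param gender optional: restrict to `"male"` or `"female"`.
#' @param conf confidence level.
#' @return Tibble: `bmi_class` (code), `label`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
class_means <- function(cohort, gender = NULL, conf = 0.95) {
  if (!"bmi_class" %in% names(cohort)) cohort <- augment_cohort(cohort)
  keep <- !cohort$excluded & is.finite(cohort$rmr_kcal_day)
  if (!is.null(gender)) keep <- keep & cohort$gender == gender
  dat <- cohort[keep, ]
  per_kg <- dat$rmr_kcal_day / dat$weight_kg
  rows <- lapply(1:5, function(k) {
    v <- per_kg[dat$bmi_class == k]
    n <- length(v)
    if (n == 0) return(NULL)
    half <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(v) / sqrt(n) else 0
    tibble::tibble(bmi_class = k, label = bmi_class_label(k),
                   mean = mean(v), ci_lo = mean(v) - half,
                   ci_hi = mean(v) + half, n = n)
  })
  empty <- which(vapply(rows, is.null, TRUE))
  if (length(empty)) {
    warning("empty BMI class(es) omitted: ",
            paste(bmi_class_label(empty), collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(rows)
}

#' Fit the BMI-class power-law RMR equation
#'
#' Ordinary least squares of log10(RMR per kg) on log10(BMI-class code),
#' yielding the power form `RMR (kcal/kg/day) = c * code^b` with
#' `c = 10^intercept` and `b` the log-log slope. The canonical regressor is
#' the integer class code 1--5 (the only reading under which class means
#' reproduce the power form with near-unit R-squared); a non-canonical
#' `regressor = "bmi"` mode regresses on the class mean of measured BMI
#' instead.
#'
#' The default fits the five class means (one point per class). With
#' `level = "subject"`, individual per-kg values are fitted instead, weighted
#' equally, as a sensitivity analysis.
#'
#' @param x either a class-means tibble from [class_means()] or an augmented
#'   cohort (from which means are computed, honouring `scope`).
#' @param scope `"both"`, `"male"` or `"female"` (used when `x` is a cohort).
#' @param level `"class"` (default: fit class means) or `"subject"`.
#' @param regressor `"code"` (canonical) or `"bmi"` (non-canonical).
#' @return Object of class `power_law_fit`: `c`, `b`, `intercept`, `slope`
#'   (log10 space), `r2`, `scope`, `level`, `regressor`, `n_points`.
#' @examples
#' means <- tibble::tibble(bmi_class = 1:5,
#'                         mean = c(21.7, 19.1, 18.2, 17.4, 17.0))
#' fit_power_law(means) # slope about -0.152, c about 21.5
#' @export
fit_power_law <- function(x, scope = c("both", "male", "female"),
                          level = c("class", "subject"),
                          regressor = c("code", "bmi")) {
  scope <- match.arg(scope)
  level <- match.arg(level)
  regressor <- match.arg(regressor)
  g <- if (scope == "both") NULL else scope

  if (all(c("bmi_class", "mean") %in% names(x)) && !"weight_kg" %in% names(x)) {
    pts <- tibble::tibble(code = x$bmi_class, y = x$mean)
    if (regressor == "bmi") {
      stop("regressor = 'bmi' needs a cohort, not precomputed class means",
           call. = FALSE)
    }
    xx <- pts$code
  } else {
    cohort <- if ("bmi_class" %in% names(x)) x else augment_cohort(x)
    if (level == "subject") {
      keep <- !cohort$excluded & is.finite(cohort$rmr_kcal_day)
      if (!is.null(g)) keep <- keep & cohort$gender == g
      dat <- cohort[keep, ]
      pts <- tibble::tibble(code = dat$bmi_class,
                            y = dat$rmr_kcal_day / dat$weight_kg)
      xx <- if (regressor == "bmi") dat$bmi else pts$code
    } else {
      cm <- class_means(cohort, gender = g)
      pts <- tibble::tibble(code = cm$bmi_class, y = cm$mean)
      xx <- if (regressor == "bmi") {
        keep <- !cohort$excluded & is.finite(cohort$rmr_kcal_day)
        if (!is.null(g)) keep <- keep & cohort$gender == g
        tapply(cohort$bmi[keep], cohort$bmi_class[keep], mean)[
          as.character(pts$code)]
      } else {
        pts$code
      }
    }
  }
  if (length(unique(pts$code)) < 3) {
    stop("need data in at least 3 BMI classes to fit", call. = FALSE)
  }
  fit <- stats::lm(log10(pts$y) ~ log10(xx))
  # suppress the "essentially perfect fit" note summary.lm emits on
  # noiseless input; r2 = 1 is a legitimate outcome here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(c = unname(10^coef(fit)[1]), b = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
         r2 = r2, scope = scope, level = level,
         regressor = regressor, n_points = length(pts$y)),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit> RMR (kcal/kg/day) = %.4g * (class)^%.4g  [%s]\n",
              x$c, x$b, x$scope))
  cat(sprintf("  log10(RMR) = %.4g %+.4g log10(class);  R2 = %.1f%%  (%d %s points)\n",
              x$intercept, x$slope, 100 * x$r2, x$n_points,
              if (x$level == "class") "class-mean" else "subject"))
  invisible(x)
}

#' Predict daily RMR from the fitted BMI-class equation
#'
#' Evaluates `c * code^b` kcal/kg/day and scales by body weight.
#'
#' @param fit a `power_law_fit`.
#' @param bmi_class integer class code 1--5 (class 0 is excluded from the
#'   equation's domain).
#' @param weight_kg body weight; default 1 returns the per-kg rate.
#' @return kcal/day (or kcal/kg/day for unit weight).
#' @examples
#' f <- fit_power_law(tibble::tibble(bmi_class = 1:5,
#'                                   mean = 20 * (1:5)^-0.2))
#' predict_new_equation(f, 1, 70) # c * 70 at class 1
#' @export
predict_new_equation <- function(fit, bmi_class, weight_kg = 1) {
  stopifnot(inherits(fit, "power_law_fit"))
  if (any(bmi_class == 0)) {
    stop("underweight (class 0) is outside the fitted equation's domain",
         call. = FALSE)
  }
  if (any(!bmi_class %in% 1:5)) {
    stop("bmi_class must be a code in 1..5", call. = FALSE)
  }
  fit$c * bmi_class^fit$b * weight_kg
}
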