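#' Box-Cox power-transformation exponent
#'
#' Profile-likelihood estimate of the Box-Cox lambda for a positive sample,
#' over the grid [-1, 1.5] in steps of 0.01. Lambda near 0.5 corresponds to a
#' square-root transform, lambda near 0 to a log transform; absolute-bias
#' distributions typically land between the two.
#'
#' @param values strictly positive numeric vector, n >= 10.
#' @param grid lambda grid to profile over.
#' @return List with `lambda` (grid maximiser of the profile log-likelihood)
#'   and `transformed` (the Box-Cox transform `(x^l - 1)/l`, or `log(x)` at
#'   l = 0).
#' @examples
#' set.seed(1)
#' boxcox_lambda(rnorm(500, 10)^2)$lambda # close to 0.5
#' @export
boxcox_lambda <- function(values, grid = seq(-1, 1.5, by = 0.01)) {
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("Box-Cox requires strictly positive finite values", call. = FALSE)
  }
  if (length(values) < 10) stop("need n >= 10 values", call. = FALSE)
  if (stats::sd(values) == 0) {
    stop("degenerate input: values are constant", call. = FALSE)
  }
  prof <- MASS::boxcox(values ~ 1, lambda = grid, plotit = FALSE,
                       interp = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  list(lambda = lambda, transformed = boxcox_transform(values, lambda))
}

#' @rdname boxcox_lambda
#' @param lambda transformation exponent.
#' @export
boxcox_transform <- function(values, lambda) {
  if (abs(lambda) < 1e-12) log(values) else (values^lambda - 1) / lambda
}

#' Regress transformed absolute bias on gender, BMI class and age group
#'
#' Models per-subject absolute bias |RMRe - RMRm|, first normalised by a
#' Box-Cox transform (lambda estimated by [boxcox_lambda()]), as a main-effects
#' linear model in the three categorical factors, then removes factors by
#' backward elimination: at each step the factor with the largest whole-factor
#' F-test p-value above `alpha` is dropped (ties broken in the order gender,
#' BMI class, age group), until all retained factors are significant.
#'
#' Reference levels are the first level of each factor (female, normal
#' weight, ages 10-18). Factor levels with fewer than 2 observations are
#' collapsed into the nearest populated level with a warning.
#'
#' @param abs_bias strictly positive per-subject absolute bias, kcal/day.
#' @param factors data frame / tibble with columns `gender`, `bmi_class`
#'   (codes 1-5), `age_group` (codes 1-5); underweight subjects must already
#'   be excluded.
#' @param alpha whole-factor significance threshold for elimination
#'   (default 0.05).
#' @param lambda optional fixed lambda; default estimates it from `abs_bias`.
#' @return An object of class `bias_model`: `lambda`, `retained` (character),
#'   `p_values` (named, for the retained factors), `elimination` (tibble of
#'   the drop sequence), `effects` (per-level means of transformed bias for
#'   every factor), and the final `fit` (an `lm`, or `NULL` if no factor
#'   survives).
#' @export
fit_bias_model <- function(abs_bias, factors, alpha = 0.05, lambda = NULL) {
  stopifnot(all(c("gender", "bmi_class", "age_group") %in% names(factors)),
            nrow(factors) == length(abs_bias))
  if (any(!is.finite(abs_bias)) || any(abs_bias <= 0)) {
    stop("abs_bias must be finite and strictly positive", call. = FALSE)
  }
  if (is.null(lambda)) {
    bc <- boxcox_lambda(abs_bias)
    lambda <- bc$lambda
    y <- bc$transformed
  } else {
    y <- boxcox_transform(abs_bias, lambda)
  }
  dat <- data.frame(
    y = y,
    gender = factor(factors$gender, levels = genders),
    bmi_class = factor(factors$bmi_class, levels = 1:5,
                       labels = names(bmi_class_levels)[-1]),
    age_group = factor(factors$age_group, levels = 1:5,
                       labels = names(age_group_levels))
  )
  for (f in c("gender", "bmi_class", "age_group")) {
    dat[[f]] <- collapse_sparse_levels(dat[[f]], f)
  }

  factor_order <- c("gender", "bmi_class", "age_group")
  retained <- factor_order[vapply(factor_order,
                                  function(f) nlevels(dat[[f]]) > 1, TRUE)]
  dropped <- setdiff(factor_order, retained)
  elim <- list()
  repeat {
    if (!length(retained)) break
    fit <- stats::lm(stats::reformulate(retained, "y"), data = dat)
    dr <- stats::drop1(fit, test = "F")
    p <- dr[["Pr(>F)"]][-1]
    names(p) <- rownames(dr)[-1]
    p[is.na(p)] <- 1 # aliased factor contributes nothing: drop first
    p <- p[order(match(names(p), factor_order))] # deterministic tie-break
    worst <- names(p)[which.max(p)]
    if (p[[worst]] <= alpha) break
    elim[[length(elim) + 1]] <- tibble::tibble(
      step = length(elim) + 1L, dropped = worst, p = p[[worst]]
    )
    retained <- setdiff(retained, worst)
  }
  if (length(retained)) {
    fit <- stats::lm(stats::reformulate(retained, "y"), data = dat)
    dr <- stats::drop1(fit, test = "F")
    p_values <- stats::setNames(dr[["Pr(>F)"]][-1], rownames(dr)[-1])
  } else {
    fit <- NULL
    p_values <- stats::setNames(numeric(0), character(0))
  }
  effects <- lapply(stats::setNames(factor_order, factor_order), function(f) {
    means <- tapply(dat$y, dat[[f]], mean)
    tibble::tibble(level = names(means), mean_transformed = as.numeric(means),
                   n = as.integer(table(dat[[f]])))
  })
  structure(
    list(lambda = lambda, retained = retained, p_values = p_values,
         elimination = dplyr::bind_rows(elim), effects = effects,
         alpha = alpha, fit = fit),
    class = "bias_model"
  )
}

collapse_sparse_levels <- function(x, name) {
  x <- droplevels(x)
  counts <- table(x)
  sparse <- names(counts)[counts > 0 & counts < 2]
  if (length(sparse)) {
    warning(name, ": level(s) ", paste(sparse, collapse = ", "),
            " have < 2 observations; collapsed into the adjacent level",
            call. = FALSE)
    lv <- levels(x)
    for (s in sparse) {
      i <- match(s, lv)
      target <- if (i > 1) lv[i - 1] else lv[i + 1]
      levels(x)[i] <- target
      lv <- levels(x)
    }
    x <- droplevels(x)
  }
  x
}

#' @export
print.bias_model <- function(x, ...) {
  cat("<bias_model> lambda =", format(x$lambda, digits = 3), "\n")
  if (length(x$retained)) {
    cat("  retained:",
        paste(sprintf("%s (p = %.3g)", names(x$p_values), x$p_values),
              collapse = ", "), "\n")
  } else {
    cat("  no factor retained at alpha =", x$alpha, "\n")
  }
  invisible(x)
}

#' Main-effects profile of a fitted bias model
#'
#' Per-level means of the transformed absolute bias for each factor, the
#' quantity drawn in a main-effects plot.
#'
#' @param result a `bias_model` from [fit_bias_model()].
#' @param retained_only if TRUE (default) only retained factors are returned.
#' @return Long tibble: `factor`, `level`, `mean_transformed`, `n`.
#' @export
effects_profile <- function(result, retained_only = TRUE) {
  stopifnot(inherits(result, "bias_model"))
  keep <- if (retained_only && length(result$retained)) {
    result$retained
  } else {
    names(result$effects)
  }
  dplyr::bind_rows(lapply(keep, function(f) {
    tibble::tibble(factor = f, result$effects[[f]])
  }))
}

#' Bias-factor models for every equation
#'
#' Runs [fit_bias_model()] on |RMRe - RMRm| for each prediction column,
#' returning one summary row per equation (lambda, retained factors and their
#' p-values) plus the fitted objects.
#'
#' @inheritParams agreement_table
#' @param alpha elimination threshold.
#' @return List with `table` (tidy per-equation summary) and `models` (named
#'   list of `bias_model` objects).
#' @export
bias_model_table <- function(pred, cohort, alpha = 0.05) {
  if (!"excluded" %in% names(cohort)) cohort <- augment_cohort(cohort)
  keep <- !cohort$excluded & is.finite(cohort$rmr_kcal_day)
  eq_names <- setdiff(names(pred), "id")
  models <- list()
  rows <- list()
  for (nm in eq_names) {
    e <- pred[[nm]][keep]
    if (all(is.na(e))) next
    ab <- abs(e - cohort$rmr_kcal_day[keep])
    ab[ab <= 0] <- min(ab[ab > 0]) / 2 # exact ties are measure-zero; guard
    m <- fit_bias_model(ab, cohort[keep, c("gender", "bmi_class", "age_group")],
                        alpha = alpha)
    models[[nm]] <- m
    p <- function(f) if (f %in% names(m$p_values)) m$p_values[[f]] else NA_real_
    rows[[nm]] <- tibble::tibble(
      equation = nm, lambda = m$lambda,
      p_gender = p("gender"), p_bmi_class = p("bmi_class"),
      p_age_group = p("age_group")
    )
  }
  list(table = dplyr::bind_rows(rows), models = models)
}
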