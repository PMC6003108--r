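#' Load a prediction-equation configuration
#'
#' Parses a YAML equation library (see the bundled
#' `system.file("extdata", "equations.yaml", package = "rmragree")` for the
#' format) into a validated list of equation specifications. Each equation is
#' a set of per-(gender, age-bracket) linear coefficient rows producing
#' kcal/day; a `placeholder: true` equation may carry no rows and is skipped
#' by [predict_all()] with a warning.
#'
#' Validation enforces: known covariate names, both genders covered, and
#' integer age brackets per gender that tile 10--120 without gap or overlap.
#'
#' @param path path to a YAML config.
#' @return A named list of `rmr_equation` objects (fields `name`, `category`,
#'   `covariates`, `height_unit`, `placeholder`, `rows`).
#' @export
load_equation_config <- function(path) {
  if (!file.exists(path)) stop("equation config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$equations)) stop("config has no 'equations' block", call. = FALSE)
  specs <- lapply(cfg$equations, parse_equation_spec)
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

known_covariates <- c("weight", "height", "age", "age_group", "gender", "bmi")

parse_equation_spec <- function(block) {
  name <- block$name
  if (is.null(name) || !nzchar(name)) stop("equation without a name", call. = FALSE)
  bad <- setdiff(unlist(block$covariates), known_covariates)
  if (length(bad)) {
    stop(name, ": unknown covariate(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rows <- block$rows
  placeholder <- isTRUE(block$placeholder)
  if (!length(rows) && !placeholder) {
    stop(name, ": no coefficient rows and not marked placeholder", call. = FALSE)
  }
  rows <- lapply(rows, function(r) {
    r$gender <- parse_gender(r$gender)
    if (is.na(r$gender)) stop(name, ": bad gender in row", call. = FALSE)
    for (f in c("intercept", "weight", "height", "age", "bmi")) {
      if (is.null(r[[f]])) r[[f]] <- 0
    }
    r
  })
  if (length(rows)) {
    for (g in genders) {
      grows <- Filter(function(r) r$gender == g, rows)
      if (!length(grows)) {
        stop(name, ": no coefficient row for ", g, call. = FALSE)
      }
      covered <- integer(0)
      for (r in grows) {
        span <- seq.int(r$age_min, r$age_max)
        if (length(intersect(span, covered))) {
          stop(name, ": overlapping age brackets for ", g, call. = FALSE)
        }
        covered <- c(covered, span)
      }
      if (!all(10:120 %in% covered)) {
        stop(name, ": age brackets leave gaps in 10-120 for ", g, call. = FALSE)
      }
    }
  }
  structure(
    list(name = name,
         category = as.integer(block$category),
         covariates = unlist(block$covariates),
         height_unit = if (is.null(block$height_unit)) "m" else block$height_unit,
         placeholder = placeholder,
         rows = rows),
    class = "rmr_equation"
  )
}

#' @export
print.rmr_equation <- function(x, ...) {
  cat("<rmr_equation> ", x$name, " (category ", x$category, "; ",
      paste(x$covariates, collapse = ", "), ")\n", sep = "")
  if (x$placeholder) cat("  placeholder: no coefficients available\n")
  else cat("  ", length(x$rows), " coefficient row(s)\n", sep = "")
  invisible(x)
}

#' @rdname load_equation_config
#' @details `default_equations()` loads the library shipped with the package:
#'   Harris-Benedict 1919 (`H-B`), its Roza-Shizgal revision (`H-B_Rev`), the
#'   abbreviated per-kg Harris-Benedict rule (`H-B_Abbr`), Mifflin-St Jeor,
#'   Owen, Schofield (weight-only), FAO-WHO-UNU weight+height (`FWU1`) and
#'   weight-only (`FWU2`), plus a `Harrington` placeholder (its BMI-based
#'   coefficients are not publicly tabulated, so it cannot predict).
#' @export
default_equations <- function() {
  load_equation_config(
    system.file("extdata", "equations.yaml", package = "rmragree")
  )
}

match_row <- function(spec, gender, age) {
  age <- as.integer(floor(age))
  for (r in spec$rows) {
    if (r$gender == gender && age >= r$age_min && age <= r$age_max) return(r)
  }
  NULL
}

#' Predict RMR for subjects with one equation
#'
#' Evaluates the linear coefficient row matching each subject's gender and
#' integer age bracket. Height is stored in metres and converted to the
#' equation's unit internally.
#'
#' @param spec an `rmr_equation` from [load_equation_config()].
#' @param gender,age,weight_kg,height_m subject covariates (vectorised).
#' @return Estimated RMR in kcal/day.
#' @examples
#' eqs <- default_equations()
#' predict_rmr(eqs$Owen, "male", 40, 177, 1.80)  # 879 + 10.2*177 = 2684.4
#' @export
predict_rmr <- function(spec, gender, age, weight_kg, height_m) {
  stopifnot(inherits(spec, "rmr_equation"))
  if (spec$placeholder) {
    stop(spec$name, ": placeholder equation has no coefficients", call. = FALSE)
  }
  n <- max(length(gender), length(age), length(weight_kg), length(height_m))
  gender <- rep_len(parse_gender(gender), n)
  age <- rep_len(age, n); weight_kg <- rep_len(weight_kg, n)
  height_m <- rep_len(height_m, n)
  h <- if (spec$height_unit == "cm") height_m * 100 else height_m
  bmi <- weight_kg / height_m^2
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (is.na(gender[i])) stop("unrecognised gender", call. = FALSE)
    r <- match_row(spec, gender[i], age[i])
    if (is.null(r)) {
      stop(spec$name, ": no coefficient row for ", gender[i], " age ", age[i],
           call. = FALSE)
    }
    out[i] <- r$intercept + r$weight * weight_kg[i] + r$height * h[i] +
      r$age * age[i] + r$bmi * bmi[i]
  }
  if (any(!is.finite(out) | out <= 0)) {
    warning(spec$name, ": non-positive prediction produced", call. = FALSE)
  }
  out
}

#' Build the per-subject, per-equation prediction matrix
#'
#' Predicts every subject (including excluded underweight subjects -- the
#' exclusion flag only applies to downstream statistics) with every equation.
#' Placeholder equations yield an all-`NA` column with a warning.
#'
#' @param cohort subject tibble (augmented or not).
#' @param specs list of `rmr_equation` objects, e.g. [default_equations()].
#' @return A tibble with `id` plus one kcal/day column per equation, carrying
#'   the spec list as attribute `"specs"`.
#' @export
predict_all <- function(cohort, specs) {
  stopifnot(nrow(cohort) > 0)
  if (!length(specs)) {
    warning("empty equation list; returning id-only matrix", call. = FALSE)
    return(tibble::tibble(id = as.character(cohort$id)))
  }
  out <- tibble::tibble(id = as.character(cohort$id))
  for (spec in specs) {
    if (spec$placeholder) {
      warning(spec$name, ": placeholder equation, predictions set to NA",
              call. = FALSE)
      out[[spec$name]] <- NA_real_
    } else {
      out[[spec$name]] <- predict_rmr(spec, cohort$gender, cohort$age,
                                      cohort$weight_kg, cohort$height_m)
    }
  }
  attr(out, "specs") <- specs
  out
}
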