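#' @title BMI class and age group codings
#' @description Level tables used throughout the package. BMI classes follow
#'   WHO cutoffs; codes 1--5 (normal weight through obesity class III) are the
#'   regression codes of the BMI-class RMR equation, while code 0
#'   (underweight) is retained in the data model but flagged as excluded from
#'   all statistics.
#' @format `bmi_class_levels` is a named integer vector (labels as names);
#'   `age_group_levels` likewise for the five age groups.
#' @name codings
NULL

#' @rdname codings
#' @export
bmi_class_levels <- c(
  underweight = 0L, normal = 1L, overweight = 2L,
  obese_I = 3L, obese_II = 4L, obese_III = 5L
)

#' @rdname codings
#' @export
age_group_levels <- c(
  "10-18" = 1L, "19-30" = 2L, "31-45" = 3L, "46-60" = 4L, ">60" = 5L
)

genders <- c("male", "female")
education_levels <- c("primary", "secondary", "tertiary", "unknown")

#' Classify body mass index into WHO classes
#'
#' Computes BMI as weight / height^2 and assigns the WHO class with
#' lower-inclusive cutoffs 18.5, 25, 30, 35, 40. Vectorised.
#'
#' @param weight_kg body weight in kilograms, strictly positive.
#' @param height_m standing height in metres, strictly positive.
#' @return Integer class codes 0--5 (see [bmi_class_levels]), with the labels
#'   attached as a `"labels"` attribute-free factor via [bmi_class_label()].
#' @examples
#' classify_bmi(96, 2.00)   # BMI 24 -> normal weight, code 1
#' classify_bmi(42.7, 1.60) # BMI 16.7 -> underweight, code 0 (excluded)
#' @export
classify_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be finite and strictly positive", call. = FALSE)
  }
  bmi <- weight_kg / height_m^2
  # findInterval is lower-inclusive: BMI exactly 25 -> overweight; the tiny
  # offset keeps boundary BMIs computed with floating-point error (e.g.
  # 24.99999999999999 from an exactly-25 weight/height pair) in the upper class
  as.integer(findInterval(bmi + 1e-9, c(18.5, 25, 30, 35, 40)))
}

#' @rdname classify_bmi
#' @param code integer BMI class code 0--5.
#' @export
bmi_class_label <- function(code) {
  names(bmi_class_levels)[match(code, bmi_class_levels)]
}

#' Classify age into study age groups
#'
#' Integer ages are partitioned gap-free into 10--18, 19--30, 31--45, 46--60
#' and >60 (codes 1--5). Ages below 10 are outside the supported range.
#'
#' @param age age in whole years, at least 10.
#' @return Integer group codes 1--5 (see [age_group_levels]).
#' @examples
#' classify_age(c(18, 19, 77)) # 1, 2, 5
#' @export
classify_age <- function(age) {
  if (any(!is.finite(age)) || any(age < 10)) {
    stop("age must be >= 10 years (paediatric ages unsupported)", call. = FALSE)
  }
  as.integer(findInterval(age, c(10, 19, 31, 46, 61)))
}

#' @rdname classify_age
#' @param code integer age-group code 1--5.
#' @export
age_group_label <- function(code) {
  names(age_group_levels)[match(code, age_group_levels)]
}

parse_gender <- function(x) {
  key <- c(m = "male", male = "male", f = "female", female = "female")
  unname(key[tolower(trimws(as.character(x)))])
}

#' Derive BMI, BMI class, age group and exclusion flag for a cohort
#'
#' @param cohort a subject tibble with columns `gender`, `age`, `weight_kg`,
#'   `height_m` (as produced by [read_cohort()] or [generate_cohort()]).
#' @return The cohort with added columns `bmi`, `bmi_class` (integer code),
#'   `bmi_label`, `age_group` (integer code), `age_label` and `excluded`
#'   (TRUE for underweight subjects, which every analysis stage drops).
#' @export
augment_cohort <- function(cohort) {
  stopifnot(all(c("gender", "age", "weight_kg", "height_m") %in% names(cohort)))
  cohort$bmi <- cohort$weight_kg / cohort$height_m^2
  cohort$bmi_class <- classify_bmi(cohort$weight_kg, cohort$height_m)
  cohort$bmi_label <- bmi_class_label(cohort$bmi_class)
  cohort$age_group <- classify_age(cohort$age)
  cohort$age_label <- age_group_label(cohort$age_group)
  cohort$excluded <- cohort$bmi_class == 0L
  cohort
}

subject_columns <- c("id", "gender", "age", "weight_kg", "height_m",
                     "education", "rmr_kcal_day")

validate_rows <- function(raw) {
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  gender <- parse_gender(raw$gender)
  age <- suppressWarnings(as.numeric(raw$age))
  weight <- suppressWarnings(as.numeric(raw$weight_kg))
  height <- suppressWarnings(as.numeric(raw$height_m))
  rmr <- if ("rmr_kcal_day" %in% names(raw)) {
    suppressWarnings(as.numeric(raw$rmr_kcal_day))
  } else {
    rep(NA_real_, n)
  }
  edu <- if ("education" %in% names(raw)) {
    tolower(trimws(as.character(raw$education)))
  } else {
    rep("unknown", n)
  }
  edu[is.na(edu) | edu == ""] <- "unknown"

  flag <- function(bad, why) {
    bad <- bad & is.na(reason)
    reason[bad] <<- why
  }
  flag(is.na(gender), "unrecognised gender token")
  flag(is.na(age) | age < 0, "unparseable or negative age")
  flag(!is.na(age) & age < 10, "age below supported range (10 y)")
  flag(is.na(weight) | weight <= 0, "weight must be a positive number")
  flag(is.na(height) | height <= 0, "height must be a positive number")
  flag(!edu %in% education_levels, "unknown education level")
  flag(!is.na(rmr) & rmr <= 0, "measured RMR must be positive if present")

  ok <- is.na(reason)
  subjects <- tibble::tibble(
    id = as.character(raw$id)[ok],
    gender = gender[ok],
    age = age[ok],
    weight_kg = weight[ok],
    height_m = height[ok],
    education = edu[ok],
    rmr_kcal_day = rmr[ok]
  )
  rejected <- tibble::tibble(row = which(!ok), reason = reason[!ok])
  list(subjects = subjects, rejected = rejected)
}

#' Read a subject table from delimited text
#'
#' Expects a header row with columns `id, gender, age, weight_kg, height_m,
#' education, rmr_kcal_day` (education and measured RMR optional); gender
#' tokens `M/F/male/female` are accepted case-insensitively. Lines starting
#' with `#` are treated as comments. Rows violating the subject invariants
#' (positive weight/height, age >= 10, positive RMR when present) are dropped
#' with a per-row reason rather than failing the whole file.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab from
#'   the header line.
#' @return A subject tibble with attributes `rejected` (tibble of row numbers
#'   and reasons) and `n_rejected`; [augment_cohort()] adds derived columns.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("cohort: file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(path, n = 25L)
    first <- first[!startsWith(first, "#")][1]
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           colClasses = "character", stringsAsFactors = FALSE)
  mandatory <- c("id", "gender", "age", "weight_kg", "height_m")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols)) {
    stop("cohort: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- validate_rows(raw)
  if (nrow(out$rejected)) {
    message(nrow(out$rejected), " row(s) rejected; see attr(x, 'rejected')")
  }
  subjects <- out$subjects
  attr(subjects, "rejected") <- out$rejected
  attr(subjects, "n_rejected") <- nrow(out$rejected)
  subjects
}

#' Write a subject table as CSV
#'
#' Writes the canonical column set; extra derived columns are dropped so that
#' [read_cohort()] round-trips the file. Optional `comment` lines (e.g. the
#' generator seed) are prefixed with `#`.
#'
#' @param cohort subject tibble.
#' @param path output path.
#' @param comment optional character vector of comment lines.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, comment = NULL) {
  keep <- intersect(subject_columns, names(cohort))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(as.data.frame(cohort[keep]), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
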