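# Small in-code fixtures shared across tests.

# A hand-written 6-subject cohort spanning genders, age groups and BMI classes
# (one underweight subject to exercise the exclusion flag).
toy_cohort <- function() {
  tibble::tibble(
    id = sprintf("T%02d", 1:6),
    gender = c("male", "male", "female", "female", "female", "male"),
    age = c(25, 70, 15, 40, 55, 33),
    weight_kg = c(96, 85, 45, 70, 110, 130),
    height_m = c(2.00, 1.70, 1.60, 1.65, 1.62, 1.80),
    education = c("tertiary", "primary", "secondary", "tertiary",
                  "secondary", "unknown"),
    rmr_kcal_day = c(2000, 1600, 1100, 1400, 1900, 2300)
  )
}

# Cohort with a deterministic per-kg power law: RMRm = weight * c * code^b.
power_law_cohort <- function(c0 = 20, b0 = -0.2, n_per_class = 8) {
  heights <- 1.70
  # weights chosen to hit BMI classes 1..5 at height 1.70 (BMI = w / 2.89)
  bmi_targets <- c(21, 27, 32, 37, 45)
  rows <- lapply(1:5, function(k) {
    w <- bmi_targets[k] * heights^2 + seq(-1, 1, length.out = n_per_class)
    tibble::tibble(
      id = sprintf("P%d_%d", k, seq_len(n_per_class)),
      gender = rep(c("male", "female"), length.out = n_per_class),
      age = 30 + k, weight_kg = w, height_m = heights,
      education = "secondary",
      rmr_kcal_day = w * c0 * k^b0
    )
  })
  rmragree::augment_cohort(dplyr::bind_rows(rows))
}

write_temp_config <- function(txt) {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  writeLines(txt, path)
  path
}
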