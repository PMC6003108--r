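test_that("default library loads nine equations with Harrington as placeholder", {
  eqs <- default_equations()
  expect_length(eqs, 9L)
  expect_setequal(names(eqs), c("H-B", "H-B_Rev", "H-B_Abbr", "Mifflin",
                                "Owen", "Schofield", "FWU1", "FWU2",
                                "Harrington"))
  expect_true(eqs$Harrington$placeholder)
  expect_error(predict_rmr(eqs$Harrington, "male", 30, 80, 1.8), "placeholder")
  # re-loading and re-predicting is bit-identical
  co <- augment_cohort(toy_cohort())
  p1 <- suppressWarnings(predict_all(co, eqs))
  p2 <- suppressWarnings(predict_all(co, default_equations()))
  expect_identical(p1, p2)
})

test_that("weight-only equations reproduce hand values at the cohort extremes", {
  eqs <- default_equations()
  expect_equal(predict_rmr(eqs$Owen, "male", 40, 177, 1.80), 879 + 10.2 * 177)
  expect_equal(predict_rmr(eqs$Owen, "female", 40, 42.7, 1.60),
               795 + 7.18 * 42.7)
  expect_equal(predict_rmr(eqs[["H-B_Abbr"]], "male", 40, 177, 1.80), 24 * 177)
  expect_equal(predict_rmr(eqs[["H-B_Abbr"]], "female", 40, 42.7, 1.60),
               22.8 * 42.7)
})

test_that("Mifflin gender offset and H-B hand evaluation are exact", {
  eqs <- default_equations()
  m <- predict_rmr(eqs$Mifflin, "male", 40, 80, 1.75)
  f <- predict_rmr(eqs$Mifflin, "female", 40, 80, 1.75)
  expect_equal(m - f, 166)
  expect_equal(m, 9.99 * 80 + 6.25 * 175 - 4.92 * 40 + 5)
  expect_equal(predict_rmr(eqs[["H-B"]], "male", 30, 70, 1.80),
               66.4730 + 13.7516 * 70 + 5.0033 * 180 - 6.7550 * 30)
})

test_that("age-bracket dispatch puts shared boundaries in the lower bracket", {
  eqs <- default_equations()
  # age 18 -> junior Schofield row; age 19 -> 19-30 row; age 30 stays there
  expect_equal(predict_rmr(eqs$Schofield, "male", 18, 60, 1.7),
               658.2 + 17.686 * 60)
  expect_equal(predict_rmr(eqs$Schofield, "male", 19, 60, 1.7),
               692.2 + 15.057 * 60)
  expect_equal(predict_rmr(eqs$Schofield, "male", 30, 60, 1.7),
               692.2 + 15.057 * 60)
  expect_equal(predict_rmr(eqs$Schofield, "male", 31, 60, 1.7),
               873.1 + 11.472 * 60)
  # FWU1 uses height in metres
  expect_equal(predict_rmr(eqs$FWU1, "female", 65, 60, 1.60),
               -302 + 9.2 * 60 + 637 * 1.60)
})

test_that("all predicting equations are non-decreasing in weight", {
  eqs <- default_equations()
  w <- seq(45, 170, by = 5)
  for (nm in setdiff(names(eqs), "Harrington")) {
    for (g in c("male", "female")) {
      for (a in c(15, 25, 40, 70)) {
        p <- predict_rmr(eqs[[nm]], g, a, w, 1.70)
        expect_true(all(diff(p) >= 0), label = paste(nm, g, a))
      }
    }
  }
})

test_that("prediction matrix is complete, with NA column for placeholders", {
  co <- augment_cohort(toy_cohort())
  eqs <- default_equations()
  expect_warning(pred <- predict_all(co, eqs), "Harrington")
  expect_equal(nrow(pred), nrow(co))
  expect_equal(ncol(pred), 10L) # id + 9 equations
  vals <- as.matrix(pred[setdiff(names(pred), c("id", "Harrington"))])
  expect_true(all(is.finite(vals) & vals > 0))
  expect_true(all(is.na(pred$Harrington)))
  expect_warning(empty <- predict_all(co, list()), "empty")
  expect_equal(names(empty), "id")
})

test_that("config validation rejects overlaps, gaps and unknown covariates", {
  base <- c("equations:",
            "  - name: Bad",
            "    category: 3",
            "    covariates: [weight, age_group, gender]",
            "    rows:")
  row <- function(g, a1, a2) {
    sprintf("      - {gender: %s, age_min: %d, age_max: %d, intercept: 100, weight: 10}",
            g, a1, a2)
  }
  # overlapping brackets
  p1 <- write_temp_config(c(base, row("male", 18, 30), row("male", 25, 120),
                            row("female", 10, 120)))
  expect_error(load_equation_config(p1), "overlap")
  # gap (nothing below 19 for male)
  p2 <- write_temp_config(c(base, row("male", 19, 120), row("female", 10, 120)))
  expect_error(load_equation_config(p2), "gap")
  # missing female rows entirely
  p3 <- write_temp_config(c(base, row("male", 10, 120)))
  expect_error(load_equation_config(p3), "female")
  # unknown covariate name
  p4 <- write_temp_config(c("equations:",
                            "  - name: Bad",
                            "    category: 1",
                            "    covariates: [weight, shoe_size]",
                            "    rows:", row("male", 10, 120),
                            row("female", 10, 120)))
  expect_error(load_equation_config(p4), "unknown covariate")
})
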