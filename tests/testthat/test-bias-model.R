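test_that("Box-Cox lambda recovers known transformations", {
  set.seed(101)
  sq <- rnorm(10000, mean = 12, sd = 1)^2    # sqrt-normalisable
  expect_equal(boxcox_lambda(sq)$lambda, 0.5, tolerance = 0.1)
  ln <- exp(rnorm(10000, 0, 0.5))            # log-normalisable
  expect_equal(boxcox_lambda(ln)$lambda, 0, tolerance = 0.1)
  expect_error(boxcox_lambda(rep(3, 50)), "constant")
  expect_error(boxcox_lambda(c(-1, 1:20)), "positive")
  expect_error(boxcox_lambda(1:5), "n >= 10")
  # transform limits: lambda 0 is the log
  expect_equal(boxcox_transform(c(1, 10), 0), log(c(1, 10)))
  expect_equal(boxcox_transform(4, 0.5), (2 - 1) / 0.5)
})

sim_factors <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    gender = sample(c("male", "female"), n, replace = TRUE),
    bmi_class = sample(1:5, n, replace = TRUE),
    age_group = sample(1:5, n, replace = TRUE)
  )
}

test_that("a strong pure gender effect is the only factor retained", {
  fac <- sim_factors(300, seed = 7)
  set.seed(8)
  bias <- exp(rnorm(300, 0, 0.2)) * ifelse(fac$gender == "male", 400, 100)
  m <- fit_bias_model(bias, fac)
  expect_equal(m$retained, "gender")
  expect_lt(m$p_values[["gender"]], 1e-6)
})

test_that("alpha = 1 keeps every factor and alpha = 0 drops them all", {
  fac <- sim_factors(200, seed = 21)
  set.seed(22)
  bias <- exp(rnorm(200, 5, 0.3))
  keep_all <- fit_bias_model(bias, fac, alpha = 1)
  expect_setequal(keep_all$retained, c("gender", "bmi_class", "age_group"))
  drop_all <- fit_bias_model(bias, fac, alpha = 0)
  expect_length(drop_all$retained, 0L)
  expect_null(drop_all$fit)
})

test_that("OLS coefficients match a normal-equations oracle", {
  fac <- sim_factors(120, seed = 31)
  set.seed(32)
  bias <- exp(rnorm(120, 5, 0.3)) * (1 + 0.1 * fac$bmi_class)
  m <- fit_bias_model(bias, fac, alpha = 1, lambda = 0.5)
  X <- stats::model.matrix(m$fit)
  y <- boxcox_transform(bias, 0.5)
  beta <- solve(t(X) %*% X, t(X) %*% y)   # independent closed form
  expect_equal(unname(coef(m$fit)), as.numeric(beta), tolerance = 1e-8)
})

test_that("effects profile is flat at the grand mean for balanced equal groups", {
  fac <- tibble::tibble(gender = rep(c("male", "female"), each = 10),
                        bmi_class = rep(1:5, 4),
                        age_group = rep(1:5, times = 4))
  bias <- rep(c(10, 30), 10) # same {10,30} mix in every gender level
  m <- fit_bias_model(bias, fac, alpha = 1, lambda = 1)
  prof <- effects_profile(m, retained_only = FALSE)
  gender_rows <- prof[prof$factor == "gender", ]
  expect_equal(gender_rows$mean_transformed,
               rep(mean(boxcox_transform(bias, 1)), 2))
})

test_that("a monotone BMI effect is retained with a monotone profile", {
  fac <- sim_factors(400, seed = 41)
  set.seed(42)
  bias <- exp(rnorm(400, 0, 0.15)) * (50 + 120 * fac$bmi_class)
  m <- fit_bias_model(bias, fac)
  expect_true("bmi_class" %in% m$retained)
  prof <- effects_profile(m)
  bmi_prof <- prof[prof$factor == "bmi_class", ]
  expect_true(all(diff(bmi_prof$mean_transformed) > 0))
})

test_that("sparse factor levels are collapsed with a warning", {
  fac <- tibble::tibble(gender = c(rep("female", 29), "male"),
                        bmi_class = rep(1:5, 6),
                        age_group = rep(rep(1:5, each = 2), 3))
  set.seed(5)
  bias <- exp(rnorm(30, 4, 0.3))
  expect_warning(m <- fit_bias_model(bias, fac, alpha = 1), "collapsed")
  expect_false("gender" %in% m$retained) # single level left, not testable
})

test_that("per-equation bias table reports lambda and factor p-values", {
  co <- generate_cohort(seed = 19)
  pred <- suppressWarnings(predict_all(co, default_equations()))
  bm <- suppressWarnings(bias_model_table(pred, co))
  expect_equal(nrow(bm$table), 8L)
  expect_true(all(is.finite(bm$table$lambda)))
  # the per-kg equation (H-B Abbr) must show a BMI-class effect on a cohort
  # whose per-kg RMR declines with class
  expect_lt(bm$table$p_bmi_class[bm$table$equation == "H-B_Abbr"], 1e-6)
  hba <- bm$models[["H-B_Abbr"]]
  expect_true("bmi_class" %in% hba$retained)
})
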