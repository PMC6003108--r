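test_that("default generator reproduces the target cohort composition", {
  co <- generate_cohort(seed = 1)
  expect_equal(nrow(co), 383L)
  expect_equal(sum(co$gender == "male"), 105L)
  expect_equal(sum(co$gender == "female"), 278L)
  cfg <- default_cohort_config()
  for (g in c("male", "female")) {
    for (v in c("age", "weight", "height")) {
      col <- c(age = "age", weight = "weight_kg", height = "height_m")[[v]]
      x <- co[[col]][co$gender == g]
      expect_true(all(x >= cfg[[v]][[g]][["low"]] - 0.5 &
                        x <= cfg[[v]][[g]][["high"]] + 0.5),
                  label = paste(g, v, "within truncation bounds"))
    }
  }
  expect_gte(length(unique(co$bmi_class[co$bmi_class > 0])), 4L)
})

test_that("the generator is deterministic in the seed", {
  a <- generate_cohort(seed = 99)
  b <- generate_cohort(seed = 99)
  expect_identical(a, b)
  c <- generate_cohort(seed = 100)
  expect_false(identical(a$weight_kg, c$weight_kg))
})

test_that("zero noise and flat exponent give an exact per-kg constant", {
  cfg <- default_cohort_config()
  cfg$noise_sd <- 0
  cfg$rmr_model <- list(male = c(c = 20, b = 0), female = c(c = 20, b = 0))
  co <- generate_cohort(cfg, seed = 5)
  expect_equal(co$rmr_kcal_day / co$weight_kg, rep(20, nrow(co)),
               tolerance = 1e-12)
})

test_that("impossible truncation bounds and negative noise are rejected", {
  cfg <- default_cohort_config()
  cfg$weight$male[c("low", "high")] <- c(100, 90)
  expect_error(generate_cohort(cfg, seed = 1), "low < high")
  cfg2 <- default_cohort_config()
  cfg2$noise_sd <- -0.1
  expect_error(generate_cohort(cfg2, seed = 1), "noise_sd")
})

test_that("empirical marginals match the truncated-normal oracle at large n", {
  cfg <- default_cohort_config()
  cfg$n <- c(male = 10000L, female = 0L)
  co <- generate_cohort(cfg, seed = 77)
  # analytic mean of a truncated normal, the independent oracle
  tn_mean <- function(p) {
    a <- (p[["low"]] - p[["mean"]]) / p[["sd"]]
    b <- (p[["high"]] - p[["mean"]]) / p[["sd"]]
    p[["mean"]] + p[["sd"]] * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  for (v in c("weight", "height")) {
    col <- c(weight = "weight_kg", height = "height_m")[[v]]
    x <- co[[col]]
    expect_lt(abs(mean(x) - tn_mean(cfg[[v]]$male)), 3 * sd(x) / sqrt(length(x)))
  }
  # rounding ages to integers adds at most 0.5 beyond the 3-SE band
  a <- co$age
  expect_lt(abs(mean(a) - tn_mean(cfg$age$male)), 0.5 + 3 * sd(a) / sqrt(length(a)))
  # weight-height coupling is positive as configured
  expect_gt(cor(co$weight_kg, co$height_m), 0.2)
})

test_that("per-kg RMR follows the configured class power law up to noise", {
  cfg <- default_cohort_config()
  cfg$noise_sd <- 0
  co <- generate_cohort(cfg, seed = 55)
  keep <- !co$excluded
  per_kg <- co$rmr_kcal_day[keep] / co$weight_kg[keep]
  expected <- ifelse(co$gender[keep] == "male",
                     25.41 * co$bmi_class[keep]^-0.2115,
                     21.09 * co$bmi_class[keep]^-0.1786)
  expect_equal(per_kg, expected, tolerance = 1e-12)
})

test_that("bias injections create the requested factor-structured shift", {
  cfg <- default_cohort_config()
  cfg$noise_sd <- 0
  cfg$bias_injections <- list(gender = c(male = 0.1, female = 0))
  co <- generate_cohort(cfg, seed = 61)
  per_kg <- co$rmr_kcal_day / co$weight_kg
  base <- ifelse(co$gender == "male",
                 25.41 * pmax(co$bmi_class, 1)^-0.2115,
                 21.09 * pmax(co$bmi_class, 1)^-0.1786)
  ratio <- log10(per_kg / base)
  expect_equal(as.numeric(tapply(ratio, co$gender, mean)[c("male", "female")]),
               c(0.1, 0), tolerance = 1e-10)
})

test_that("education is tertiary-enriched in the normal-weight class", {
  cfg <- default_cohort_config()
  cfg$n <- c(male = 4000L, female = 4000L)
  co <- generate_cohort(cfg, seed = 83)
  p_norm <- mean(co$education[co$bmi_class == 1] == "tertiary")
  p_rest <- mean(co$education[co$bmi_class > 1] == "tertiary")
  expect_gt(p_norm, p_rest)
})
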