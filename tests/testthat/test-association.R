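test_that("inverse-normal transform hits target moments and is rank-invariant", {
  v <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(v[2], 0)
  expect_equal(v[1], -v[3])

  set.seed(10)
  x <- exp(stats::rnorm(1000))  # standard-lognormal draws
  tx <- inverse_normal_transform(x)
  expect_lt(abs(mean(tx)), 1e-8)
  expect_lt(abs(stats::sd(tx) - 1), 0.02)
  skew <- mean((tx - mean(tx))^3) / stats::sd(tx)^3
  expect_lt(abs(skew), 0.1)

  # any monotone transform of the input yields the identical output
  expect_equal(inverse_normal_transform(log(x)), tx)
  expect_equal(inverse_normal_transform(rank(x)), tx)

  # missing values pass through; ties get average ranks
  w <- inverse_normal_transform(c(5, NA, 5, 1))
  expect_true(is.na(w[2]))
  expect_equal(w[1], w[3])
  expect_error(inverse_normal_transform(rep(2, 10)), "constant")
  expect_error(inverse_normal_transform(c(1, NA, NA)), ">= 2")
})

test_that("linear_assoc recovers an exact relationship and flags collinearity", {
  x <- seq(1, 20)
  fit <- suppressWarnings(linear_assoc(2 * x, x))  # perfect-fit warning
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lt(fit$se, 1e-10)
  expect_lt(fit$p, 1e-12)

  set.seed(11)
  covs <- data.frame(c1 = stats::rnorm(50))
  covs$c2 <- covs$c1 * 2  # collinear
  expect_error(linear_assoc(stats::rnorm(50), stats::rnorm(50), covs),
               "collinear")
})

test_that("linear_assoc drops incomplete rows per model and counts them", {
  set.seed(12)
  y <- stats::rnorm(100)
  x <- stats::rnorm(100)
  y[1:10] <- NA
  fit <- linear_assoc(y, x)
  expect_equal(fit$n, 90)
  expect_equal(fit$n_dropped, 10)
})

test_that("null p-values from linear_assoc are uniform", {
  set.seed(13)
  pvals <- replicate(500, {
    y <- stats::rnorm(300)
    x <- stats::rbinom(300, 2, 0.3)
    linear_assoc(y, x)$p
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("beta on the INT-transformed trait is invariant to monotone trait rescaling", {
  set.seed(14)
  x <- stats::rbinom(400, 2, 0.4)
  y <- 0.3 * x + stats::rnorm(400)
  f1 <- linear_assoc(y, x, transform = TRUE)
  f2 <- linear_assoc(exp(y / 2), x, transform = TRUE)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-12)
})

test_that("logistic_assoc equals the closed-form 2x2 odds ratio and guards degeneracy", {
  wc <- factor(rep(c("obese", "normal"), each = 50),
               levels = c("normal", "overweight", "obese"))
  x <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  fit <- logistic_assoc(wc, "obese", "normal", x)
  expect_equal(fit$odds_ratio, (40 * 40) / (10 * 10), tolerance = 1e-6)
  expect_equal(fit$n_cases, 50)
  expect_equal(fit$n_controls, 50)
  expect_true(fit$ci_low <= fit$odds_ratio && fit$odds_ratio <= fit$ci_high)

  # separation is an error, not a silent estimate
  xs <- c(rep(1, 50), rep(0, 50))
  expect_error(suppressWarnings(logistic_assoc(wc, "obese", "normal", xs)))
  # empty class
  wc2 <- factor(rep("normal", 100), levels = levels(wc))
  expect_error(logistic_assoc(wc2, "obese", "normal", x), "empty")
})

test_that("logistic CI covers the null about 95% of the time under no association", {
  set.seed(15)
  covered <- replicate(300, {
    wc <- factor(sample(c("obese", "normal"), 300, replace = TRUE),
                 levels = c("normal", "overweight", "obese"))
    x <- stats::rbinom(300, 2, 0.3)
    fit <- logistic_assoc(wc, "obese", "normal", x)
    fit$ci_low <= 1 && 1 <= fit$ci_high
  })
  expect_gt(mean(covered), 0.90)
  expect_lt(mean(covered), 0.99)
})

test_that("explained variance follows 2f(1-f)b^2 and is symmetric in f", {
  expect_equal(explained_variance(0.5, 1), 0.5)
  expect_equal(explained_variance(0.2, 0.1), 0.0032)
  expect_equal(explained_variance(0, 0.5), 0)
  expect_equal(explained_variance(1, 0.5), 0)
  f <- seq(0, 1, by = 0.05)
  expect_equal(explained_variance(f, 0.3), explained_variance(1 - f, 0.3))
  expect_error(explained_variance(1.2, 0.1), "f must")
})

test_that("BMI-to-weight conversion and Bonferroni arithmetic are exact", {
  expect_equal(bmi_effect_to_weight(0.11, 1.7), 318)
  expect_equal(bmi_effect_to_weight(1.0, 1.0), 1000)
  expect_equal(bmi_effect_to_weight(0, 1.93), 0)
  expect_equal(bmi_effect_to_weight(0.11, 1.7, round_grams = FALSE), 317.9)
  expect_error(bmi_effect_to_weight(0.1, 0), "height")

  expect_equal(bonferroni_threshold(0.05, 125), 0.0004)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 28), 0.05 / 28)
  expect_error(bonferroni_threshold(0.05, 0), "m must")
})

test_that("covariate presets build the documented designs", {
  ph <- data.frame(age = c(55, 60), sex = factor(c("male", "female")),
                   region = factor(c("Beijing", "Shanghai")),
                   pc1 = c(0.1, -0.1), pc2 = c(0, 1))
  full <- covariate_set(ph, "bmi-set")
  expect_equal(names(full), c("age", "age2", "sex", "region", "pc1", "pc2"))
  expect_equal(full$age2, ph$age^2)
  expect_equal(full$sex, c(0L, 1L))
  expect_equal(full$region, c(0L, 1L))
  dxa <- covariate_set(ph, "dxa-set")
  expect_equal(names(dxa), c("age", "age2", "sex"))
  expect_equal(attr(full, "reference_levels"),
               c(sex = "male", region = "Beijing"))
})
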