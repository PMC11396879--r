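make_designed_na <- function() {
  set.seed(61)
  df <- data.frame(x = rnorm(15), age = runif(15, 20, 60),
                   sex = factor(rep(c("female", "male"), length.out = 15)),
                   bmi = runif(15, 18, 35))
  df$y <- rnorm(15)
  df$x[3] <- NA; df$bmi[7] <- NA
  df
}

make_design <- function(n, seed) {
  set.seed(seed)
  data.frame(
    group = factor(sample(c("HC", "RR", "PMS"), n, replace = TRUE),
                   levels = c("HC", "RR", "PMS")),
    age = runif(n, 20, 70),
    sex = factor(sample(c("female", "male"), n, replace = TRUE)),
    bmi = runif(n, 18, 40)
  )
}

test_that("an exactly linear outcome is fitted with zero residual", {
  df <- make_design(60, seed = 1)
  df$y <- 5 + 2 * (df$group == "RR") - 3 * (df$group == "PMS") +
    0.1 * df$age + 1.5 * (df$sex == "male") - 0.2 * df$bmi
  fit <- fit_adjusted_ols(df, "y", "group")
  expect_lt(fit$ss_error, 1e-16 * stats::var(df$y) * nrow(df))
  est <- fit$coefficients
  expect_equal(est$estimate[est$term == "groupRR"], 2, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "groupPMS"], -3, tolerance = 1e-8)
  expect_equal(est$estimate[est$term == "age"], 0.1, tolerance = 1e-8)
})

test_that("coefficients match the normal-equations oracle on a hand fixture", {
  # 12-subject fixture with simple numbers, checkable by hand
  df <- data.frame(
    y = c(10, 12, 9, 14, 11, 13, 20, 18, 22, 7, 8, 15),
    x = c(1, 2, 1, 3, 2, 3, 6, 5, 7, 0, 1, 4),
    age = c(30, 40, 35, 50, 45, 55, 60, 42, 38, 33, 47, 52),
    sex = factor(c("female", "male", "female", "male", "female", "male",
                   "female", "male", "female", "male", "female", "male")),
    bmi = c(22, 25, 27, 30, 24, 28, 26, 23, 29, 21, 31, 25)
  )
  fit <- fit_adjusted_ols(df, "y", "x")
  X <- stats::model.matrix(y ~ x + age + sex + bmi, df)
  beta <- oracle_ols_coef(X, df$y)
  expect_equal(fit$coefficients$estimate, unname(beta), tolerance = 1e-8)
})

test_that("coefficients match the normal-equations oracle on random designs", {
  for (r in 1:100) {
    df <- make_design(25, seed = 200 + r)
    set.seed(300 + r)
    df$x <- rnorm(25)
    df$y <- rnorm(25, sd = 3)
    fit <- fit_adjusted_ols(df, "y", "x")
    X <- stats::model.matrix(y ~ x + age + sex + bmi, df)
    expect_equal(fit$coefficients$estimate,
                 unname(oracle_ols_coef(X, df$y)), tolerance = 1e-8)
  }
})

test_that("OLS is linear in the outcome: the BCAA identity holds per dataset", {
  co <- simulate_cohort(small_config(), seed = 17)
  fits <- lapply(c("valine", "leucine", "isoleucine", "bcaa"), function(v) {
    fit_adjusted_ols(co, v, "group")
  })
  get <- function(fit, term) fit$coefficients$estimate[fit$coefficients$term == term]
  for (term in c("groupRR", "groupPMS")) {
    expect_equal(get(fits[[4]], term),
                 get(fits[[1]], term) + get(fits[[2]], term) + get(fits[[3]], term),
                 tolerance = 1e-10)
  }
})

test_that("generalized eta-squared matches the model-comparison oracle", {
  for (r in 1:25) {
    df <- make_design(40, seed = 400 + r)
    set.seed(500 + r)
    df$y <- rnorm(40, sd = 2) + as.numeric(df$group) + 0.05 * df$age
    fit <- fit_adjusted_ols(df, "y", "group")
    full <- stats::lm(y ~ group + age + sex + bmi, df)
    for (tm in c("group", "age", "sex", "bmi")) {
      reduced <- stats::lm(stats::as.formula(paste(
        "y ~", paste(setdiff(c("group", "age", "sex", "bmi"), tm),
                     collapse = " + "))), df)
      ss_term <- sum(stats::residuals(reduced)^2) - sum(stats::residuals(full)^2)
      ss_err <- sum(stats::residuals(full)^2)
      expect_equal(generalized_eta_squared(fit, tm),
                   ss_term / (ss_term + ss_err), tolerance = 1e-10)
    }
  }
  expect_error(generalized_eta_squared(fit_adjusted_ols(df, "y", "group"), "nope"),
               "not in model")
})

test_that("Type II sums of squares agree with car::Anova", {
  skip_if_not_installed("car")
  df <- make_design(80, seed = 9)
  set.seed(10)
  df$y <- rnorm(80, sd = 2) + 2 * (df$group == "PMS") + 0.03 * df$age
  fit <- fit_adjusted_ols(df, "y", "group")
  ca <- car::Anova(stats::lm(y ~ group + age + sex + bmi, df), type = 2)
  for (tm in c("group", "age", "sex", "bmi")) {
    expect_equal(fit$terms$sum_sq[fit$terms$term == tm],
                 ca[tm, "Sum Sq"], tolerance = 1e-8)
    expect_equal(fit$terms$p_value[fit$terms$term == tm],
                 ca[tm, "Pr(>F)"], tolerance = 1e-8)
  }
})

test_that("eta-squared is invariant to affine rescaling of outcome and covariates", {
  df <- make_design(60, seed = 77)
  set.seed(78)
  df$y <- rnorm(60) + (df$group == "RR")
  base <- fit_adjusted_ols(df, "y", "group")
  df2 <- df
  df2$y <- 100 * df2$y - 7
  df2$age <- df2$age / 10 + 3
  df2$bmi <- 2 * df2$bmi
  scaled <- fit_adjusted_ols(df2, "y", "group")
  expect_equal(scaled$terms$eta_sq, base$terms$eta_sq, tolerance = 1e-10)
  expect_equal(scaled$terms$p_value, base$terms$p_value, tolerance = 1e-10)
})

test_that("an orthogonal extra covariate leaves coefficients unchanged", {
  n <- 40
  set.seed(55)
  x <- rnorm(n)
  z <- rnorm(n)
  z <- residuals(stats::lm(z ~ x))      # orthogonal to x by construction
  z <- z - mean(z)
  df <- data.frame(x = x, z = z, y = rnorm(n) + 2 * x)
  with_z <- fit_adjusted_ols(df, "y", "x", covariates = "z")
  # orthogonality of z to both x and the intercept preserves beta_x
  only_x <- stats::lm(y ~ x, df)
  expect_equal(with_z$coefficients$estimate[with_z$coefficients$term == "x"],
               unname(stats::coef(only_x)[["x"]]), tolerance = 1e-10)
})

test_that("degenerate designs and scarce data are rejected with named columns", {
  df <- make_design(30, seed = 3)
  df$y <- rnorm(30)
  df$bmi2 <- 2 * df$bmi
  expect_error(fit_adjusted_ols(df, "y", "group",
                                covariates = c("age", "sex", "bmi", "bmi2")),
               "bmi2")
  expect_error(fit_adjusted_ols(df[1:8, ], "y", "group"), "complete cases")
  df$age[1:25] <- NA
  expect_error(fit_adjusted_ols(df, "y", "group"), "complete cases")
  fit <- fit_adjusted_ols(make_designed_na(), "y", "x")
  expect_identical(fit$n_dropped, 2L)
  expect_identical(fit$n, 13L)
})

test_that("effect-size labels follow the inclusive thresholds", {
  expect_identical(effect_size_label(0.0099), "negligible")
  expect_identical(effect_size_label(0.01), "small")
  expect_identical(effect_size_label(0.039), "small")
  expect_identical(effect_size_label(0.06), "medium")
  expect_identical(effect_size_label(0.139), "medium")
  expect_identical(effect_size_label(0.14), "large")
  expect_identical(effect_size_label(1), "large")
  expect_error(effect_size_label(1.2), "\\[0, 1\\]")
  expect_error(effect_size_label(-0.1), "\\[0, 1\\]")
})

test_that("perfect single-predictor fit gives eta-squared of 1, null effect 0", {
  df <- data.frame(x = 1:12, y = 3 + 2 * (1:12))
  fit <- fit_adjusted_ols(df, "y", "x", covariates = character(0))
  expect_equal(generalized_eta_squared(fit, "x"), 1)
  # orthogonal noise-free design with a zero-effect term
  df2 <- expand.grid(x = c(-1, 1), z = c(-1, 1))
  df2 <- df2[rep(1:4, 3), ]
  df2$y <- 2 * df2$x          # z has exactly zero effect
  fit2 <- fit_adjusted_ols(df2, "y", "z", covariates = "x")
  expect_equal(generalized_eta_squared(fit2, "z"), 0)
})
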