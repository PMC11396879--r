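test_that("demographics honor group sizes, grids, and flag consistency", {
  cfg <- cohort_config()
  demo <- generate_demographics(cfg, seed = 1)
  expect_identical(as.integer(table(demo$group)), c(153L, 187L, 91L))
  expect_identical(anyDuplicated(demo$subject_id), 0L)
  expect_true(all(demo$age >= 18))
  expect_true(all(demo$bmi > 0))
  expect_identical(demo$obese, demo$bmi >= 30)

  hc <- demo[demo$group == "HC", ]
  ms <- demo[demo$group != "HC", ]
  expect_true(all(is.na(hc$edss)) && all(is.na(hc$t25fw)) &&
                all(is.na(hc$disease_duration)))
  expect_false(anyNA(ms$edss))
  expect_true(all(ms$edss >= 0 & ms$edss <= 10))
  expect_true(all(ms$edss * 2 == round(ms$edss * 2)))  # half-point grid
  expect_true(all(ms$t25fw > 0))
  expect_true(all(ms$disease_duration > 0))
})

test_that("same config and seed reproduce the cohort bit-for-bit", {
  cfg <- small_config()
  a <- simulate_cohort(cfg, seed = 123)
  b <- simulate_cohort(cfg, seed = 123)
  expect_identical(a, b)
  c <- simulate_cohort(cfg, seed = 124)
  expect_false(identical(a$valine, c$valine))
})

test_that("EDSS distributions land on the configured median/IQR targets", {
  cfg <- cohort_config(n = c(hc = 5L, rr = 4000L, pms = 4000L))
  demo <- generate_demographics(cfg, seed = 21)
  rr <- demo$edss[demo$group == "RR"]
  pms <- demo$edss[demo$group == "PMS"]
  # discretization to the half-point grid allows a half-step of slack
  expect_lte(abs(stats::median(rr) - 2.5), 0.5)
  expect_lte(abs(stats::quantile(rr, 0.25) - 1.5), 0.5)
  expect_lte(abs(stats::quantile(rr, 0.75) - 3.5), 0.5)
  expect_lte(abs(stats::median(pms) - 6.0), 0.5)
  expect_lte(abs(stats::quantile(pms, 0.75) - 6.5), 0.5)
})

test_that("large-sample demographic means converge to configured targets", {
  cfg <- cohort_config(n = c(hc = 10000L, rr = 10L, pms = 10L))
  demo <- generate_demographics(cfg, seed = 8)
  hc <- demo[demo$group == "HC", ]
  # truncation at 18 shifts the mean up by sd * phi(z) / (1 - Phi(z))
  z <- (18 - 45.9) / 13.9
  mu_trunc <- 45.9 + 13.9 * stats::dnorm(z) / (1 - stats::pnorm(z))
  se_age <- 13.9 / sqrt(10000)
  expect_lt(abs(mean(hc$age) - mu_trunc), 3 * se_age)
  expect_lt(abs(mean(hc$sex == "female") - 0.556), 3 * sqrt(0.556 * 0.444 / 10000))
})

test_that("metabolites follow baseline + shift with controllable residuals", {
  # zero shifts and zero residual SD reproduce the baselines exactly
  mets0 <- list(valine = list(mean = 230, sd = 0, beta_rr = 0, beta_pms = 0))
  cfg0 <- shift_config(n = c(hc = 10L, rr = 10L, pms = 10L), metabolites = mets0)
  demo0 <- generate_demographics(cfg0, seed = 3)
  pan0 <- generate_metabolites(demo0, cfg0, seed = 3)
  expect_identical(pan0$valine, rep(230, 30))

  # group-mean differences converge to the configured shifts at large n
  mets <- list(valine = list(mean = 230, sd = 40, beta_rr = -18.2, beta_pms = -21.6))
  cfg <- shift_config(n = c(hc = 8000L, rr = 8000L, pms = 8000L), metabolites = mets)
  demo <- generate_demographics(cfg, seed = 5)
  pan <- generate_metabolites(demo, cfg, seed = 5)
  mns <- tapply(pan$valine, pan$group, mean)
  se_diff <- 40 * sqrt(2 / 8000)
  expect_lt(abs((mns[["RR"]] - mns[["HC"]]) - (-18.2)), 3 * se_diff)
  expect_lt(abs((mns[["PMS"]] - mns[["HC"]]) - (-21.6)), 3 * se_diff)
  expect_identical(sum(attr(pan, "n_floored")), 0L)  # mean is > 5 SD above 0
})

test_that("metabolite flooring is counted and warned, never silent", {
  mets <- list(trace = list(mean = 1, sd = 5, beta_rr = 0, beta_pms = 0))
  cfg <- shift_config(n = c(hc = 200L, rr = 10L, pms = 10L), metabolites = mets)
  demo <- generate_demographics(cfg, seed = 4)
  expect_warning(pan <- generate_metabolites(demo, cfg, seed = 4), "floored")
  expect_gt(attr(pan, "n_floored")[["trace"]], 0L)
  expect_true(all(pan$trace >= 0))
})

test_that("outcome-coupled scores are affine in the predictor when noiseless", {
  cfg <- small_config()
  demo <- generate_demographics(cfg, seed = 6)
  ms <- demo[demo$group != "HC", ]
  s <- generate_outcome_coupled_scores(ms, "edss", intercept = 50,
                                       slope = 0.946, noise_sd = 0, seed = 1)
  expect_equal(as.numeric(s), 50 + 0.946 * ms$edss)
  sw <- generate_outcome_coupled_scores(ms, "log10_t25fw", intercept = 40,
                                        slope = 5.34, noise_sd = 0, seed = 1)
  expect_equal(as.numeric(sw), 40 + 5.34 * log10(ms$t25fw))
  # zero slope: fitted slope centered at zero across replicates
  est <- vapply(1:40, function(r) {
    ms$score <- as.numeric(generate_outcome_coupled_scores(
      ms, "edss", intercept = 50, slope = 0, noise_sd = 5, seed = r))
    fit <- fit_adjusted_ols(ms, "score", "edss")
    fit$coefficients$estimate[fit$coefficients$term == "edss"]
  }, numeric(1))
  expect_lt(abs(mean(est)), 3 * stats::sd(est) / sqrt(40))
  # predictor must be complete
  expect_error(generate_outcome_coupled_scores(demo, "edss", 50, 1, 1, seed = 1),
               "missing")
})

test_that("MRI volumetrics are reproducible, positive, and couple as configured", {
  cfg <- small_config()
  co <- simulate_cohort(cfg, seed = 31)
  expect_identical(co$gmv, simulate_cohort(cfg, seed = 31)$gmv)
  ms <- co[co$group != "HC", ]
  for (m in c("t2_lv", "t1_lv", "wbv", "gmv", "dgmv", "cv", "lvv")) {
    expect_false(anyNA(ms[[m]]))
    expect_true(all(ms[[m]] > 0))
    expect_true(all(is.na(co[[m]][co$group == "HC"])))
  }
  expect_true(all(ms$lvv < ms$wbv))

  # zero coupling: biomarker and volume essentially uncorrelated at large n
  big <- cohort_config(n = c(hc = 5L, rr = 5000L, pms = 5000L))
  bco <- simulate_cohort(big, seed = 32)
  bms <- bco[bco$group != "HC", ]
  expect_lt(abs(stats::cor(bms$glyca, bms$gmv)), 0.05)

  # coupling to an absent biomarker is a configuration error
  mri_bad <- default_mri()
  mri_bad$couplings <- list(list(measure = "gmv", biomarker = "nope", slope = -1))
  cfg_bad <- cohort_config(n = c(hc = 10L, rr = 10L, pms = 10L), mri = mri_bad)
  demo <- generate_demographics(cfg_bad, seed = 2)
  expect_error(generate_mri(demo, cfg_bad, seed = 2), "nope")
})

test_that("a configured negative biomarker-volume coupling is recovered in sign", {
  mri <- default_mri()
  mri$couplings <- list(list(measure = "gmv", biomarker = "glyca", slope = -0.4))
  cfg <- cohort_config(n = c(hc = 5L, rr = 60L, pms = 40L), mri = mri)
  signs <- vapply(1:200, function(r) {
    co <- simulate_cohort(cfg, seed = 1000 + r)
    ms <- co[co$group != "HC", ]
    fit <- fit_adjusted_ols(ms, "glyca", "gmv")
    fit$coefficients$estimate[fit$coefficients$term == "gmv"] < 0
  }, logical(1))
  expect_gt(mean(signs), 0.95)
})
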