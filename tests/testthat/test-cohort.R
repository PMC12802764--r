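test_that("covariate simulation is reproducible and respects its invariants", {
  a <- simulate_covariates(300, seed = 42)
  b <- simulate_covariates(300, seed = 42)
  c <- simulate_covariates(300, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c))

  expect_true(all(a$age_years >= 18 & a$age_years <= 100))
  expect_true(all(a$dwiv_cc > 0))
  expect_true(all(a$bpf > 0 & a$bpf < 1))
  expect_true(all(a$brain_volume_cc > 600))
  expect_equal(a$icv_cc, a$brain_volume_cc / a$bpf)
  expect_true(all(a$sex_male %in% 0:1) && all(a$htn %in% 0:1))
})

test_that("simulated marginals match the calibration targets", {
  reps <- lapply(1:30, function(r) simulate_covariates(476, seed = 100 + r))
  med_bv <- vapply(reps, function(d) median(d$brain_volume_cc), numeric(1))
  expect_lt(abs(mean(med_bv) - 1306.9), 15)
  male <- vapply(reps, function(d) mean(d$sex_male), numeric(1))
  expect_lt(abs(mean(male) - 0.653), 0.02)
  med_age <- vapply(reps, function(d) median(d$age_years), numeric(1))
  expect_lt(abs(mean(med_age) - 65.8), 2)
  med_dwiv <- vapply(reps, function(d) median(d$dwiv_cc), numeric(1))
  expect_lt(abs(mean(med_dwiv) - 2.2), 0.6)
  med_bpf <- vapply(reps, function(d) median(d$bpf), numeric(1))
  expect_lt(abs(mean(med_bpf) - 0.81), 0.01)
  r_bv_dwiv <- vapply(reps, function(d) cor(d$brain_volume_cc, log(d$dwiv_cc)),
                      numeric(1))
  expect_lt(abs(mean(r_bv_dwiv) - 0.10), 0.05)
})

test_that("the linear predictor is the documented dot product", {
  spec <- outcome_spec_bv()
  rec <- data.frame(age_years = 65.8, sex_male = 1, htn = 1, dm2 = 0,
                    nonsmoker = 1, dwiv_cc = 2.2, brain_volume_cc = 1306.9,
                    icv_cc = 1613.5, bpf = 0.81)
  by_hand <- 1.78 + 0.25 * 6.58 - 0.36 * 1 + 0.08 * 1 + 0.47 * 0 -
    0.02 * 1 + 0.35 * log(2.2) - 3.83 * 1.3069
  expect_equal(linear_predictor(rec, spec), by_hand, tolerance = 1e-12)

  zero <- outcome_model_spec("bv", intercept = 0,
                             coefficients = c(age_decades = 0, sex_male = 0,
                                              htn = 0, dm2 = 0, nonsmoker = 0,
                                              log_dwiv = 0, brain_volume_dm3 = 0))
  expect_equal(linear_predictor(rec, zero), 0)
  zero$intercept <- -2.5
  expect_equal(linear_predictor(rec, zero), -2.5)

  expect_error(linear_predictor(rec[, -1], spec), "missing fields")
  expect_error(outcome_model_spec("bv", 0, c(age_decades = 1)), "named exactly")
})

test_that("outcome generation follows the logistic model", {
  cov <- simulate_covariates(476, seed = 7)
  zero <- outcome_model_spec("bv", intercept = 0,
                             coefficients = c(age_decades = 0, sex_male = 0,
                                              htn = 0, dm2 = 0, nonsmoker = 0,
                                              log_dwiv = 0, brain_volume_dm3 = 0))
  flat <- simulate_outcomes(cov, zero, seed = 8)
  expect_lt(abs(mean(flat$mrs_gt2) - 0.5), 0.05)

  zero$intercept <- -30
  none <- simulate_outcomes(cov, zero, seed = 8)
  expect_equal(mean(none$mrs_gt2), 0)

  # prevalence is monotone in the intercept
  prev <- vapply(c(-2, 0, 2), function(c0) {
    zero$intercept <- c0
    mean(simulate_outcomes(cov, zero, seed = 9)$mrs_gt2)
  }, numeric(1))
  expect_true(all(diff(prev) > 0))

  # flipping the imaging coefficient flips the association direction
  base_cf <- c(age_decades = 0, sex_male = 0, htn = 0, dm2 = 0, nonsmoker = 0,
               log_dwiv = 0, brain_volume_dm3 = -1)
  up <- outcome_model_spec("bv", intercept = 1.3069, coefficients = base_cf)
  base_cf["brain_volume_dm3"] <- 1
  down <- outcome_model_spec("bv", intercept = -1.3069, coefficients = base_cf)
  o1 <- simulate_outcomes(cov, up, seed = 10)
  o2 <- simulate_outcomes(cov, down, seed = 10)
  expect_lt(cor(o1$brain_volume_cc, o1$mrs_gt2), 0)
  expect_gt(cor(o2$brain_volume_cc, o2$mrs_gt2), 0)
})

test_that("intercept calibration hits its target prevalence", {
  zero <- outcome_model_spec("bv", intercept = 99,
                             coefficients = c(age_decades = 0, sex_male = 0,
                                              htn = 0, dm2 = 0, nonsmoker = 0,
                                              log_dwiv = 0, brain_volume_dm3 = 0))
  expect_lt(abs(calibrate_intercept(covariate_model(), zero, 0.5, n_sim = 2e4)),
            0.01)

  spec <- outcome_spec_bpf()
  c1 <- calibrate_intercept(covariate_model(), spec, 0.248, seed = 1)
  cov <- simulate_covariates(5e4, seed = 77)
  spec$intercept <- c1
  expect_lt(abs(mean(expit(linear_predictor(cov, spec))) - 0.248), 0.01)
  # the frozen default intercept is this calibrated value
  expect_lt(abs(outcome_spec_bpf()$intercept - c1), 0.02)

  c_low <- calibrate_intercept(covariate_model(), spec, 0.1, seed = 1)
  expect_lt(c_low, c1)
  expect_error(calibrate_intercept(covariate_model(), spec, 1.2), "not TRUE")
})
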