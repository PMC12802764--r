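test_that("logistic MLE matches the 2x2 closed form and the direct-likelihood oracle", {
  # 30/100 events at x=1, 10/100 at x=0: slope and intercept in closed form
  d <- data.frame(x = rep(c(1, 0), each = 100),
                  y = c(rep(1:0, c(30, 70)), rep(1:0, c(10, 90))))
  fit <- fit_logistic(d, y ~ x)
  expect_equal(unname(fit$coefficients["x"]), log((30 * 90) / (70 * 10)),
               tolerance = 1e-8)
  expect_equal(unname(fit$coefficients["(Intercept)"]), log(10 / 90),
               tolerance = 1e-8)

  # intercept-only MLE is the logit of the sample prevalence
  fit0 <- fit_logistic(d, y ~ 1)
  expect_equal(unname(fit0$coefficients), logit(mean(d$y)), tolerance = 1e-8)

  # independent Nelder-Mead maximization of the Bernoulli likelihood
  set.seed(3)
  x <- rnorm(80)
  y <- rbinom(80, 1, expit(-0.5 + x))
  d2 <- data.frame(x = x, y = y)
  fit2 <- fit_logistic(d2, y ~ x)
  oracle <- logistic_oracle(y, cbind(1, x))
  expect_equal(unname(fit2$coefficients), oracle, tolerance = 1e-4)
})

test_that("degenerate designs and responses are refused", {
  expect_error(fit_logistic(data.frame(x = 1:5, y = c(0, 1, 2, 0, 1)), y ~ x),
               "0/1")
  expect_error(fit_logistic(data.frame(x = 1:5, y = rep(1, 5)), y ~ x),
               "both outcome classes")
  d <- data.frame(x = rnorm(50), y = rbinom(50, 1, 0.5))
  d$x2 <- 2 * d$x
  expect_error(fit_logistic(d, y ~ x + x2), "rank deficient")
  sep <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)), y = rep(0:1, each = 20))
  expect_error(suppressWarnings(fit_logistic(sep, y ~ x)), "separation")
})

test_that("BIC follows its closed form and algebra", {
  d <- data.frame(y = rep(0:1, each = 50))
  fit <- fit_logistic(d, y ~ 1)
  expect_equal(bic(fit), log(100) - 2 * 100 * log(0.5), tolerance = 1e-6)

  set.seed(8)
  d2 <- data.frame(x = rnorm(120), z = rnorm(120))
  d2$y <- rbinom(120, 1, expit(0.8 * d2$x))
  fa <- fit_logistic(d2, y ~ x)
  fb <- fit_logistic(d2, y ~ z)
  expect_equal(bic(fa) - bic(fb),
               -2 * (fa$log_likelihood - fb$log_likelihood), tolerance = 1e-10)

  # a pure-noise covariate raises BIC in the large majority of seeds
  up <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    x <- rnorm(n)
    y <- rbinom(n, 1, expit(0.5 * x))
    z <- rnorm(n)
    dd <- data.frame(x = x, y = y, z = z)
    bic(fit_logistic(dd, y ~ x + z)) > bic(fit_logistic(dd, y ~ x))
  }, logical(1))
  expect_gte(mean(up), 0.9)
})

test_that("BIC differences map to Raftery evidence categories", {
  mk <- function(ll, k = 3, n = 100, y = rep(0:1, 50)) {
    structure(list(log_likelihood = ll, k = k, n = n, y = y,
                   converged = TRUE),
              class = "fit_result")
  }
  cmp10 <- compare_models(mk(-60), mk(-55), labels = c("bpf", "bv"))
  expect_equal(cmp10$delta_bic, 10)
  expect_equal(cmp10$strength, "strong")
  expect_equal(cmp10$preferred, "bv")

  expect_equal(compare_models(mk(-60), mk(-60))$strength, "weak")
  expect_equal(compare_models(mk(-60), mk(-60))$preferred, "none")
  expect_equal(compare_models(mk(-60), mk(-59))$strength, "weak")
  expect_equal(compare_models(mk(-60), mk(-57.5))$strength, "positive")
  expect_equal(compare_models(mk(-60), mk(-49))$strength, "very strong")

  expect_error(compare_models(mk(-60), mk(-55, n = 99, y = rep(0:1, length.out = 99))),
               "different n")
  expect_error(compare_models(mk(-60), mk(-55, y = rep(1:0, 50))),
               "different outcome")
  bad <- mk(-60)
  bad$converged <- FALSE
  expect_error(bic(bad), "converge")
})

test_that("variance inflation factors quantify collinearity", {
  set.seed(12)
  ind <- data.frame(a = rnorm(476), b = rnorm(476), c = rnorm(476))
  v <- vif(ind)
  expect_true(all(v$vif >= 1 & v$vif < 1.2))

  dup <- ind
  dup$d <- dup$a
  vd <- suppressWarnings(vif(dup))  # lm warns on the perfect fit
  expect_true(vd$infinite[vd$predictor == "d"])
  expect_true(is.infinite(vd$vif[vd$predictor == "a"]))

  ind$e <- 1
  expect_error(vif(ind), "non-constant")

  # the default simulated cohort satisfies the published VIF < 2 check
  cohort <- simulate_covariates(476, seed = 2)
  mf <- strokevol:::model_frame(cohort, "bv")
  expect_true(all(vif(mf)$vif < 2))
  mf2 <- strokevol:::model_frame(cohort, "bpf")
  expect_true(all(vif(mf2)$vif < 2))
})

test_that("the Box-Tidwell check passes linear data and flags quadratic structure", {
  res_lin <- logical(20)
  res_quad <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    n <- 400
    x <- exp(rnorm(n, 0, 0.5))
    d1 <- data.frame(x = x, y = rbinom(n, 1, expit(-1 + 0.8 * x)))
    d2 <- data.frame(x = x, y = rbinom(n, 1, expit(-2 + 2.5 * (x - 1)^2)))
    f1 <- fit_logistic(d1, y ~ x)
    f2 <- suppressWarnings(fit_logistic(d2, y ~ x))
    res_lin[s] <- isTRUE(linearity_in_logit(d1, f1, "x")$pass)
    res_quad[s] <- isFALSE(suppressWarnings(linearity_in_logit(d2, f2, "x"))$pass)
  }
  expect_gte(mean(res_lin), 0.9)   # type-I behaviour at alpha = 0.05
  expect_gte(mean(res_quad), 0.6)  # power against a strong quadratic

  d <- data.frame(x = rep(2, 50), y = rbinom(50, 1, 0.5))
  f <- fit_logistic(d, y ~ 1)
  expect_error(linearity_in_logit(d, f, "x"), "constant")
})

test_that("influence diagnostics flag a manufactured contradictory outlier", {
  flags <- vapply(1:10, function(s) {
    set.seed(s)
    cohort <- simulate_cohort(476, seed = 1000 + s)
    fit <- fit_outcome_model(cohort, "bv")
    sum(influence_diagnostics(fit)$flagged)
  }, numeric(1))
  expect_gte(mean(flags == 0), 0.9)  # clean cohorts are rarely flagged

  set.seed(5)
  x <- rnorm(100)
  y <- rbinom(100, 1, expit(x))
  x[1] <- 8
  y[1] <- 0  # extreme covariate with contradictory outcome
  fit <- suppressWarnings(fit_logistic(data.frame(x = x, y = y), y ~ x))
  infl <- influence_diagnostics(fit)
  expect_true(infl$flagged[1])
  expect_true(all(infl$cooks_distance >= 0))
})

test_that("the no-intercept agreement slope behaves like the published ICV comparison", {
  x <- seq(1200, 1900, length.out = 40)
  # lm warns on the exact fits; the zero SE is the point of the check
  exact <- suppressWarnings(no_intercept_agreement(x, 0.944 * x))
  expect_equal(exact$slope, 0.944, tolerance = 1e-12)
  expect_equal(exact$se, 0, tolerance = 1e-10)
  expect_equal(suppressWarnings(no_intercept_agreement(x, x))$slope, 1,
               tolerance = 1e-12)

  covered <- vapply(1:200, function(s) {
    set.seed(s)
    xx <- runif(50, 800, 2000)
    yy <- 0.944 * xx + rnorm(50, 0, 40)
    a <- no_intercept_agreement(xx, yy)
    abs(a$slope - 0.944) <= 2 * a$se
  }, logical(1))
  expect_gte(mean(covered), 0.95)

  expect_error(no_intercept_agreement(rep(0, 5), 1:5), "identically zero")
})
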