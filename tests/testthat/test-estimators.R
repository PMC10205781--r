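test_that("first stage satisfies the normal-equations contract", {
  # exact fit when treatment equals instrument
  d <- data.frame(x = c(1, 0, 1, 0, 1), z = c(1, 0, 1, 0, 1))
  fs <- fit_first_stage(d, adjusted = FALSE)
  expect_equal(unname(fs$coefficients["z"]), 1, tolerance = 1e-10)
  expect_lt(max(abs(fs$residuals)), 1e-10)

  # toy data against the normal equations solved directly
  d <- data.frame(x = c(1, 0, 1, 0), z = c(1, 0, 0, 1))
  fs <- fit_first_stage(d, adjusted = FALSE)
  D <- cbind(1, d$z)
  oracle <- solve(t(D) %*% D, t(D) %*% d$x)
  expect_equal(unname(fs$coefficients), drop(oracle), tolerance = 1e-12)

  # constant instrument is a collinear design
  d$z <- 1
  expect_error(fit_first_stage(d, adjusted = FALSE), "collinear")
})

test_that("first-stage residuals decompose x exactly and are orthogonal to the design", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    d <- data.frame(x = rbinom(n, 1, 0.3), z = rbinom(n, 1, 0.4),
                    c1 = rnorm(n))
    if (var(d$z) == 0) next
    fs <- fit_first_stage(d, adjusted = TRUE)
    expect_lt(max(abs(fs$fitted + fs$residuals - d$x)), 1e-10)
    D <- cbind(1, d$z, d$c1)
    expect_lt(max(abs(t(D) %*% fs$residuals)), 1e-8 * n)
  }
})

test_that("the Cox fit maximizes the partial likelihood (grid-search oracle)", {
  # toy data: the written-out partial likelihood, maximized by grid search
  fit <- fit_cox_ph(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
  oracle <- grid_search_cox(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
  expect_lt(abs(fit$log_hr - oracle), 1e-3)

  # the shipped six-row fixture, single covariate x
  toy <- toy_cohort()
  fit <- fit_cox_ph(toy$t_obs, toy$event, toy$x)
  oracle <- grid_search_cox(toy$t_obs, toy$event, toy$x)
  expect_lt(abs(fit$log_hr - oracle), 1e-3)
  expect_equal(fit$hr, exp(fit$log_hr))
})

test_that("two groups with identical event-time patterns give HR = 1", {
  fit <- fit_cox_ph(c(1, 2, 1, 2), c(1, 1, 1, 1), c(1, 1, 0, 0))
  expect_lt(abs(fit$hr - 1), 1e-6)
})

test_that("the Cox estimator is consistent for exponential data with a known HR", {
  set.seed(12)
  n <- 1e5
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, rate = 0.1 * 2^x)
  fit <- fit_cox_ph(t, rep(1L, n), x)
  expect_lt(abs(fit$log_hr - log(2)), 3 * fit$se)
})

test_that("Cox fit edge cases: no events, scale equivariance", {
  expect_error(fit_cox_ph(1:4, c(0, 0, 0, 0), c(1, 0, 1, 0)), "no events")

  set.seed(13)
  n <- 200
  t <- rexp(n); e <- rbinom(n, 1, 0.7); x <- cbind(rbinom(n, 1, 0.4), rnorm(n))
  f1 <- fit_cox_ph(t, e, x)
  f2 <- fit_cox_ph(t * 3.7, e, x)
  expect_lt(abs(f1$log_hr - f2$log_hr), 1e-8)
})

test_that("two-stage IV collapses to the conventional Cox fit when Z equals X", {
  set.seed(14)
  n <- 400
  coh <- data.frame(x = rbinom(n, 1, 0.3), c1 = rnorm(n))
  coh$z <- coh$x
  coh$t_obs <- rexp(n, 0.1 * 2^coh$x)
  coh$event <- 1L

  ts <- two_stage_iv(coh, adjusted = FALSE)
  cc <- conventional_cox(coh, adjusted = FALSE)
  expect_lt(abs(ts$log_hr - cc$log_hr), 1e-8)

  # and 2SRI degenerates: residuals are identically zero
  expect_error(two_stage_residual_inclusion(coh, adjusted = FALSE),
               "residuals")
})

test_that("a null instrument is reported as a weak-instrument failure", {
  # z empirically uncorrelated with x -> constant predicted treatment
  coh <- data.frame(x = c(1, 0, 1, 0), z = c(1, 1, 0, 0),
                    t_obs = c(1, 2, 3, 4), event = 1L, c1 = 0)
  expect_error(two_stage_iv(coh, adjusted = FALSE), "instrument")
})

test_that("2SRI matches a two-parameter grid-search oracle on the fixture", {
  toy <- toy_cohort()
  fit <- two_stage_residual_inclusion(toy, adjusted = FALSE)
  fs <- fit_first_stage(toy, adjusted = FALSE)
  oracle <- grid_search_cox_2d(toy$t_obs, toy$event, toy$x, fs$residuals)
  expect_lt(abs(fit$log_hr - oracle[1]), 1e-3)
  expect_lt(abs(fit$coefficients["residual"] - oracle[2]), 1e-3)
})

test_that("the 2x2 odds ratio follows the cross-product rule", {
  z <- rep(c(1, 1, 0, 0), c(10, 5, 2, 8))
  x <- rep(c(1, 0, 1, 0), c(10, 5, 2, 8))
  expect_equal(as.numeric(odds_ratio_2x2(z, x)), 8)

  set.seed(15)
  n <- 1e6
  z <- rbinom(n, 1, 0.4); x <- rbinom(n, 1, 0.24)
  expect_lt(abs(log(odds_ratio_2x2(z, x))), 0.025)

  or <- odds_ratio_2x2(c(1, 1, 0, 0), c(1, 1, 1, 0))
  expect_true(isTRUE(attr(or, "continuity_corrected")))
  expect_equal(as.numeric(or), (2.5 * 1.5) / (0.5 * 1.5))

  expect_error(odds_ratio_2x2(c(1, 1, 1), c(1, 0, 1)), "degenerate")
})

test_that("fit objects record their covariate set and adjustment label", {
  toy <- toy_cohort()
  expect_identical(conventional_cox(toy, TRUE)$covariate_labels,
                   c("x", "c1"))
  expect_identical(two_stage_iv(toy, FALSE)$covariate_labels, "x_hat")
  expect_identical(two_stage_iv(toy, TRUE)$covariate_labels,
                   c("x_hat", "c1"))
  expect_identical(two_stage_residual_inclusion(toy, TRUE)$covariate_labels,
                   c("x", "residual", "c1"))

  fit <- conventional_cox(toy, TRUE)
  expect_identical(fit$model_label, "conventional")
  expect_true(fit$adjusted)
  expect_equal(fit$hr, exp(fit$log_hr))
  expect_named(coef(fit), fit$covariate_labels)
  expect_equal(dim(vcov(fit)), c(2L, 2L))
})
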