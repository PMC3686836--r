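test_that("M-estimators agree with OLS on clean data", {
  set.seed(11)
  x <- rnorm(200)
  X <- cbind(1, x)
  y <- 1 + 2 * x + rnorm(200)
  bols <- coef(ols_fit(X, y))
  for (fam in c("huber", "hampel", "tukey")) {
    f <- m_fit(X, y, rho_spec(fam))
    expect_true(f$converged)
    expect_equal(unname(coef(f)), unname(bols), tolerance = 0.1)
  }
})

test_that("a gross y-outlier displaces OLS but not the M-estimators", {
  d <- make_line_data(n = 20, n_outliers = 1, shift = 1000)
  for (fam in c("huber", "hampel", "tukey")) {
    f <- m_fit(d$X, d$y, rho_spec(fam))
    expect_equal(unname(coef(f))[2], 3, tolerance = 1e-3)
  }
  expect_gt(abs(coef(ols_fit(d$X, d$y))[2] - 3), 1)
})

test_that("huber with an enormous k reproduces OLS", {
  set.seed(3)
  x <- rnorm(40)
  X <- cbind(1, x)
  y <- 2 - x + rnorm(40, sd = 2)
  f <- m_fit(X, y, rho_spec("huber", 1e7))
  expect_equal(unname(coef(f)), unname(coef(ols_fit(X, y))),
               tolerance = 1e-8)
})

test_that("M-estimation matches MASS::rlm coefficients and se", {
  skip_if_not_installed("MASS")
  set.seed(21)
  x <- rnorm(120)
  y <- 1 + 2 * x + rnorm(120)
  y[1:6] <- y[1:6] + 40
  X <- cbind("(Intercept)" = 1, x = x)
  ours <- m_fit(X, y, rho_spec("huber"), tol = 1e-10)
  ref <- MASS::rlm(y ~ x, maxit = 100, acc = 1e-10)
  # rlm centres its MAD differently, so agreement is close but not exact
  expect_equal(unname(coef(ours)), unname(coef(ref)), tolerance = 1e-3)
  expect_equal(unname(ours$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 0.02)
})

test_that("final weights reflect the loss family", {
  d <- make_line_data(n = 30, n_outliers = 2, shift = 500)
  for (fam in c("hampel", "tukey")) {
    f <- m_fit(d$X, d$y, rho_spec(fam))
    expect_true(all(f$weights >= 0 & f$weights <= 1))
    expect_equal(f$weights[29:30], c(0, 0)) # beyond the redescending cutoff
    expect_equal(outlier_proportion(f), 2 / 30)
  }
})

test_that("non-convergence is flagged, not fatal", {
  set.seed(5)
  x <- rnorm(50)
  y <- 1 + x + rt(50, df = 1)
  f <- m_fit(cbind(1, x), y, rho_spec("tukey"), max_iter = 1L)
  expect_false(f$converged)
  expect_identical(f$iterations, 1L)
})

test_that("an exact fit short-circuits to the degenerate-scale path", {
  d <- make_line_data(n = 15)
  f <- m_fit(d$X, d$y, rho_spec("huber"))
  expect_equal(unname(coef(f)), c(2, 3), tolerance = 1e-10)
  expect_equal(f$scale, 0)
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-9)
})
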