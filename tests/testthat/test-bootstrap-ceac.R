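test_that("a dominant intervention bootstraps to probability one", {
  d <- tibble::tibble(
    effect = rep(1, 40),
    cost = rep(c(0, -100), each = 20), # arm 1 nb = 100, arm 0 nb = 0
    arm = rep(c(0, 1), each = 20)
  )
  p <- prob_ce_bootstrap(d, wtp = 0, method = "ols", B = 100, seed = 1)
  expect_equal(as.numeric(p), 1)
})

test_that("perfectly mirrored arms bootstrap to one half", {
  # both arms share identical effect/cost values, so the observed
  # incremental net benefit is exactly 0 and resampled INBs are
  # positive with probability one half
  set.seed(10)
  n2 <- 150
  eff <- rnorm(n2, 5, 1)
  cost <- rnorm(n2, 50, 5)
  d <- tibble::tibble(effect = rep(eff, 2), cost = rep(cost, 2),
                      arm = rep(c(0, 1), each = n2))
  p <- prob_ce_bootstrap(d, 10, "ols", B = 400, seed = 2)
  expect_lt(abs(as.numeric(p) - 0.5), 3 * sqrt(0.25 / 400) + 0.05)
})

test_that("bootstrap and regression probabilities agree on clean data", {
  cfg <- sim_config(n = 500, outlier_prop = 0, scenario = "none",
                    wtp = 12, seed = 4)
  d <- sim_nbr_data(cfg, seed = 77)
  f <- fit_nbr(d, 12, "ols", covariates = "x")
  p <- prob_ce_bootstrap(d, 12, "ols", B = 400, seed = 3,
                         covariates = "x")
  expect_equal(as.numeric(p), f$prob_ce, tolerance = 0.1)
})

test_that("bootstrap is seed-reproducible and guards small B", {
  d <- make_null_cea(n = 100, seed = 11)
  p1 <- prob_ce_bootstrap(d, 10, "ols", B = 150, seed = 9, covariates = "x")
  p2 <- prob_ce_bootstrap(d, 10, "ols", B = 150, seed = 9, covariates = "x")
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_error(prob_ce_bootstrap(d, 10, "ols", B = 50), "at least 100")
})

test_that("ceac composes single-wtp fits on a valid grid", {
  cfg <- sim_config(n = 250, outlier_prop = 0.05, scenario = "I",
                    wtp = 12, seed = 5)
  d <- sim_nbr_data(cfg, seed = 12)
  grid <- c(5, 10, 15, 20)
  cv <- ceac(d, grid, method = "huber", covariates = "x")
  expect_equal(nrow(cv), 4L)
  expect_equal(cv$wtp, grid)
  single <- fit_nbr(d, 15, "huber", covariates = "x")
  expect_equal(cv$prob_ce[cv$wtp == 15], single$prob_ce, tolerance = 1e-10)
  expect_true(all(cv$prob_ce >= 0 & cv$prob_ce <= 1))
  expect_error(ceac(d, c(10, 5)), "strictly increasing")
  expect_error(ceac(d, numeric(0)), "nonempty")
})

test_that("the zero-wtp point depends on costs alone", {
  d <- make_null_cea(n = 200, seed = 13)
  c0 <- ceac(d, c(0, 10), covariates = "x")
  d_perm <- d
  d_perm$effect <- sample(d$effect)
  c1 <- ceac(d_perm, c(0, 10), covariates = "x")
  expect_equal(c0$prob_ce[c0$wtp == 0], c1$prob_ce[c1$wtp == 0],
               tolerance = 1e-12)
})

test_that("a dominant arm pushes the whole curve toward one", {
  set.seed(14)
  n <- 200
  arm <- rep(c(0, 1), each = n / 2)
  d <- tibble::tibble(
    effect = 5 + arm + rnorm(n, sd = 0.2),
    cost = 50 - 30 * arm + rnorm(n), # intervention cheaper AND better
    arm = arm
  )
  cv <- ceac(d, c(0, 5, 10, 20))
  expect_true(all(cv$prob_ce > 0.99))
})

test_that("autoplot returns a ggplot of the curve", {
  d <- make_null_cea(n = 120, seed = 15)
  cv <- ceac(d, c(0, 10, 20), covariates = "x")
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(plot_ceac(cv), "ggplot")
})
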