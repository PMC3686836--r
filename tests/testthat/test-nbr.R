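test_that("net benefit is wtp * effect - cost", {
  d <- data.frame(effect = c(1, 2, 1), cost = c(10, 30, 0))
  expect_equal(net_benefit(d, 10), c(0, -10, 10))
  expect_equal(net_benefit(d, 0), -d$cost)
  expect_equal(net_benefit(data.frame(effect = 2, cost = 30), 50), 70)
  expect_error(net_benefit(d, -1), "nonnegative")
})

test_that("fit_nbr recovers the true incremental net benefit", {
  cfg <- sim_config(n = 5000, outlier_prop = 0, scenario = "none",
                    wtp = 12, seed = 1)
  d <- sim_nbr_data(cfg, seed = 101)
  f <- fit_nbr(d, 12, "ols", covariates = "x")
  # truth: 12 * 1 - 10 = 2; sd(inb) ~ sigma_nb * 2/sqrt(n) ~ 0.28
  expect_equal(f$inb, 2, tolerance = 3 * 0.28 / 2)
  expect_lt(f$p_value, 0.05)
  expect_equal(f$prob_ce, 1 - f$p_value)
})

test_that("exchangeable arms give a null-centred test", {
  d <- make_null_cea(n = 400, seed = 8)
  f <- fit_nbr(d, 10, "ols", covariates = "x")
  expect_lt(abs(f$inb) / (f$fit$se[2]), 3)
  expect_gt(f$p_value, 0.01)
})

test_that("wtp enters only through the net-benefit construction", {
  cfg <- sim_config(n = 300, outlier_prop = 0.1, scenario = "I",
                    wtp = 12, seed = 2)
  d <- sim_nbr_data(cfg, seed = 55)
  f12 <- fit_nbr(d, 12, "huber", covariates = "x")
  d1 <- d
  d1$effect <- 12 * d$effect
  f1 <- fit_nbr(d1, 1, "huber", covariates = "x")
  expect_equal(f12$inb, f1$inb, tolerance = 1e-8)
  expect_equal(f12$p_value, f1$p_value, tolerance = 1e-8)
})

test_that("with balanced orthogonal covariates OLS inb is the adjusted mean difference", {
  set.seed(12)
  n <- 100
  arm <- rep(c(0, 1), each = n / 2)
  x <- rep(rnorm(n / 2), 2) # identical covariate values in both arms
  d <- tibble::tibble(
    effect = 1 + arm + x + rnorm(n),
    cost = 50 + 10 * arm + x + rnorm(n),
    arm = arm, x = x
  )
  nb <- net_benefit(d, 12)
  f <- fit_nbr(d, 12, "ols", covariates = "x")
  expect_equal(f$inb, mean(nb[arm == 1]) - mean(nb[arm == 0]),
               tolerance = 1e-10)
})

test_that("tidy and glance return the documented shapes", {
  d <- make_null_cea(n = 120, seed = 3)
  f <- fit_nbr(d, 20, "tukey", covariates = "x")
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("(Intercept)", "arm", "x"))
  expect_true(all(td$std.error > 0))
  g <- glance(f)
  expect_equal(nrow(g), 1L)
  expect_equal(g$prob_ce_regression + g$p_one_sided, 1)
  expect_true(g$outlier_proportion >= 0 && g$outlier_proportion <= 1)
})

test_that("validation rejects malformed datasets", {
  d <- make_null_cea(50)
  d_bad <- d; d_bad$arm <- d_bad$arm + 1
  expect_error(fit_nbr(d_bad, 10), "0/1.*2")
  d_one <- d; d_one$arm <- 0
  expect_error(fit_nbr(d_one, 10), "both arms")
  d_na <- d; d_na$cost[c(3, 7)] <- NA
  expect_error(fit_nbr(d_na, 10), "rows: 3, 7")
  expect_error(fit_nbr(d, 10, covariates = "zzz"), "not found")
})

test_that("outlier proportion follows the weight-below-0.5 convention", {
  cfg <- sim_config(n = 400, outlier_prop = 0.1, scenario = "I",
                    wtp = 12, seed = 3)
  props <- purrr::map_dbl(1:20, function(i) {
    d <- sim_nbr_data(cfg, seed = 200 + i)
    fit_nbr(d, 12, "mm", covariates = "x", seed = i)$outlier_prop
  })
  expect_lt(abs(mean(props) - 0.10), 0.05)
  d <- sim_nbr_data(cfg, seed = 1)
  expect_true(is.na(fit_nbr(d, 12, "ols", covariates = "x")$outlier_prop))
})

test_that("fit_nbr_table reports every method x wtp cell", {
  d <- make_null_cea(n = 150, seed = 5)
  set.seed(1)
  tab <- fit_nbr_table(d, wtp = c(10, 20), methods = c("ols", "huber", "lts"),
                       covariates = "x")
  expect_equal(nrow(tab), 6L)
  expect_true(all(is.na(tab$error)))
  expect_false("prob_ce_bootstrap" %in% names(tab))
  expect_true(all(is.na(tab$outlier_proportion[tab$method == "ols"])))
})
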