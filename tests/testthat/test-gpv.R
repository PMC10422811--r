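test_that("gpq_draws is bitwise reproducible under a fixed seed", {
  s <- mutagenicity_arms("50")
  g1 <- gpq_draws(s, H = 2000, seed = 7)
  g2 <- gpq_draws(s, H = 2000, seed = 7)
  expect_identical(g1$r_xi, g2$r_xi)
  t1 <- gpv_test(s, xi0 = 0.5, direction = "less", H = 2000, seed = 11)
  t2 <- gpv_test(s, xi0 = 0.5, direction = "less", H = 2000, seed = 11)
  expect_identical(tidy(t1), tidy(t2))
})

test_that("GPQ draws concentrate at the plug-in estimate as variances vanish", {
  s <- tibble::tibble(group = c("E", "R", "P"), n = c(12, 10, 8),
                      mean = c(21, 24, 15), sd = c(1e-6, 1e-6, 1e-6))
  g <- gpq_draws(s, H = 4000, seed = 1)
  xi_hat <- g$xi_hat
  expect_equal(mean(g$r_xi, na.rm = TRUE), xi_hat, tolerance = 1e-4)
  expect_lt(diff(range(g$r_xi, na.rm = TRUE)), 1e-4)
  expect_equal(gpv_conf_limit(g, 0.95, "upper"), xi_hat, tolerance = 1e-4)
  expect_equal(gpv_conf_limit(g, 0.95, "lower"), xi_hat, tolerance = 1e-4)
  # and the plug-in agrees with the estimand evaluated at the plug-ins
  expect_equal(xi_hat, (21 - 15) / (24 - 15), tolerance = 1e-6)
})

test_that("gpv_p_value implements the indicator proportions for both directions", {
  d <- fake_draws(c(0.1, 0.2, 0.3))
  expect_equal(gpv_p_value(d, 0.5, "greater"), 1)  # all draws on the null side
  expect_equal(gpv_p_value(d, 0.5, "less"), 0)
  d2 <- fake_draws(c(0.4, 0.6))
  expect_equal(gpv_p_value(d2, 0.5, "greater"), 0.5)
  # ties at xi0 are inclusive on both sides
  d3 <- fake_draws(c(0.5, 0.5, 1.0, 0.2))
  expect_equal(gpv_p_value(d3, 0.5, "greater"), 0.75)
  expect_equal(gpv_p_value(d3, 0.5, "less"), 0.75)
})

test_that("p(greater) + p(less) = 1 + share of ties for any draw set", {
  for (seed in 1:5) {
    set.seed(seed)
    r <- round(rnorm(500, 0.8, 0.4), 2)  # rounding forces ties
    d <- fake_draws(r)
    xi0 <- round(r[1], 2)
    pg <- gpv_p_value(d, xi0, "greater"); pl <- gpv_p_value(d, xi0, "less")
    expect_equal(pg + pl, 1 + mean(r == xi0), tolerance = 1e-12)
    expect_gte(pg + pl, 1)
  }
})

test_that("gpv_p_value is nondecreasing in xi0 for direction = greater", {
  g <- gpq_draws(mutagenicity_arms("75"), H = 3000, seed = 5)
  xi0s <- seq(-0.5, 2, by = 0.1)
  ps <- vapply(xi0s, function(x) gpv_p_value(g, x, "greater"), 1)
  expect_true(all(diff(ps) >= 0))
})

test_that("gpv_conf_limit follows the inverse-ECDF order-statistic rule", {
  d <- fake_draws(as.numeric(1:100))
  expect_equal(gpv_conf_limit(d, 0.95, "upper"), 95)  # ceiling(100 * 0.95)
  expect_equal(gpv_conf_limit(d, 0.95, "lower"), 5)
  expect_equal(gpv_conf_limit(d, 0.9, "upper"), 90)
  # degenerate distribution: any level returns the constant
  dc <- fake_draws(rep(3.2, 50))
  expect_equal(gpv_conf_limit(dc, 0.95, "upper"), 3.2)
  expect_equal(gpv_conf_limit(dc, 0.5, "lower"), 3.2)
  # monotone in level
  g <- gpq_draws(mutagenicity_arms("30"), H = 2000, seed = 2)
  lv <- c(0.5, 0.8, 0.9, 0.95, 0.99)
  ups <- vapply(lv, function(l) gpv_conf_limit(g, l, "upper"), 1)
  expect_true(all(diff(ups) >= 0))
})

test_that("gpv_test validates inputs and keeps decision and limit consistent", {
  s <- mutagenicity_arms("50")
  expect_error(gpv_test(s, alpha = 1.2), "alpha")
  expect_error(gpv_test(s, alpha = 0), "alpha")
  for (dose in c("30", "75", "100")) {
    r <- gpv_test(mutagenicity_arms(dose), xi0 = 0.5, direction = "less",
                  H = 5000, seed = 3)
    expect_true(r$p_value >= 0 && r$p_value <= 1)
    # reject <=> upper limit below xi0, up to the 1/H quantile granularity
    expect_equal(r$reject, r$conf_limit < r$xi0, tolerance = 0)
  }
})

test_that("excluded draws are tallied, not silently dropped", {
  g <- gpq_draws(mutagenicity_arms("30"), H = 20000, seed = 9)
  expect_identical(length(g$r_xi), 20000L)
  n_na <- sum(is.na(g$r_xi))
  expect_identical(n_na, g$n_nonfinite + g$n_nonpos_denom)
  # this heavy-tailed configuration (tiny reference arm) does exclude some
  expect_gt(g$n_nonpos_denom, 0)
})
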