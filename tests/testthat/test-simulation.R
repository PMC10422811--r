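test_that("resolve_scenario reproduces the null construction mu_E = xi0 * delta + mu_P", {
  p <- resolve_scenario(scenario_config(delta = 9, mu_P = 16.5, tau_P = 0.5,
                                        n_total = 60, xi0 = 0.8))
  expect_equal(p$mu_E, 23.7)
  expect_equal(p$mu_R, 25.5)
  expect_equal(p$sigma2_E, 7.5^2 / 0.5)
  expect_identical(c(p$n_E, p$n_R, p$n_P), c(30L, 20L, 10L))
})

test_that("power scenarios solve mu_E so the true ratio hits xi_target", {
  cfg <- scenario_config(delta = 9, tau_P = 2, n_total = 60, xi_target = 1.2)
  p <- resolve_scenario(cfg)
  expect_equal(xi_true(p), 1.2, tolerance = 1e-9)
  # symmetric case: equal allocation and tau_R = 1 force mu_E = mu_R at xi = 1
  cfg1 <- scenario_config(delta = 9, tau_P = 1, n_total = 60,
                          allocation = c(1, 1, 1), xi_target = 1)
  p1 <- resolve_scenario(cfg1)
  expect_equal(p1$mu_E, p1$mu_R, tolerance = 1e-7)
})

test_that("scenario_config enforces the design invariants", {
  expect_error(scenario_config(tau_R = 2), "tau_R")
  expect_silent(scenario_config(tau_R = 2, allow_tau_R = TRUE))
  expect_error(scenario_config(n_total = 61), "divisible")
  expect_error(scenario_config(alpha = 0), "alpha")
})

test_that("generators match the target mean and variance in all three families", {
  mu <- 16.5; s2 <- 56.25
  n <- 4e5
  p <- population_params(mu_E = mu, mu_R = 25.5, mu_P = 16.5,
                         sigma2_E = s2, sigma2_R = s2, sigma2_P = 56.25,
                         n_E = n, n_R = 2, n_P = 2)
  # analytic excess kurtosis per family, for the variance-of-S2 bound
  kurt <- list(normal = 0,
               gamma = 6 * s2 / mu^2,
               lognormal = {
                 w <- s2 / mu^2 + 1
                 w^4 + 2 * w^3 + 3 * w^2 - 6
               })
  for (fam in c("normal", "lognormal", "gamma")) {
    set.seed(2024)
    x <- generate_three_arm(p, fam)
    v <- x$value[x$group == "E"]
    se_mean <- sqrt(s2 / n)
    se_var <- sqrt((kurt[[fam]] + 2) / n) * s2
    expect_lt(abs(mean(v) - mu), 4 * se_mean)
    expect_lt(abs(var(v) - s2), 4 * se_var)
  }
  # zero-CV limit of the log-normal is degenerate at mu
  p0 <- population_params(mu_E = mu, mu_R = 25.5, mu_P = 16.5,
                          sigma2_E = 1e-10, sigma2_R = 1e-10, sigma2_P = 1,
                          n_E = 100, n_R = 2, n_P = 2)
  x0 <- generate_three_arm(p0, "lognormal")
  expect_lt(diff(range(x0$value[x0$group == "E"])), 1e-3)
})

test_that("non-normal generation rejects nonpositive means", {
  p <- population_params(mu_E = -2, mu_R = 25.5, mu_P = 16.5,
                         sigma2_E = 1, sigma2_R = 1, sigma2_P = 1,
                         n_E = 5, n_R = 5, n_P = 5)
  expect_error(generate_three_arm(p, "gamma"), "positive means")
})

test_that("run_cell honours the seed contract and a null rejection region", {
  cfg <- scenario_config(reps = 40, H = 300, seed = 123)
  r1 <- run_cell(cfg, "gpv")
  r2 <- run_cell(cfg, "gpv")
  expect_identical(r1, r2)
  # an (almost) empty rejection region rejects nothing
  cfg0 <- scenario_config(reps = 40, H = 300, alpha = 1e-12, seed = 5)
  expect_equal(run_cell(cfg0, "delta")$rejection_rate, 0)
})

test_that("run_scenarios crosses grid rows with methods into a tidy table", {
  grid <- tibble::tibble(delta = c(9, 20), tau_P = c(0.5, 2),
                         n_total = c(60, 60), reps = 10, H = 200, seed = 1)
  out <- run_scenarios(grid, methods = c("gpv", "delta"))
  expect_identical(nrow(out), 4L)
  expect_setequal(unique(out$method), c("gpv", "delta"))
  expect_true(all(out$rejection_rate >= 0 & out$rejection_rate <= 1))
  expect_true(all(out$valid))
})

test_that("estimator_properties collapses to perfect estimation as variances vanish", {
  cfg <- scenario_config(sigma_P = 1e-5, reps = 25, H = 400, seed = 42)
  out <- estimator_properties(cfg, methods = c("gpv", "delta"))
  expect_equal(out$bias, c(0, 0), tolerance = 1e-4)
  expect_equal(out$mse, c(0, 0), tolerance = 1e-8)
  expect_equal(out$coverage, c(1, 1))
})
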