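#' Configure one simulation scenario
#'
#' A scenario cell fixes every quantity needed to simulate one three-arm
#' trial design repeatedly: the reference-over-placebo mean gain
#' `delta = mu_R - mu_P`, the placebo mean and SD, the variance ratios
#' `tau_R = sigma_R^2 / sigma_E^2` (1 by design) and
#' `tau_P = sigma_P^2 / sigma_E^2`, the total sample size and allocation,
#' the outcome distribution, the threshold `xi0`, the significance level,
#' and the Monte-Carlo sizes. Null (size) scenarios set
#' `mu_E = xi0 * delta + mu_P`; power scenarios instead give `xi_target`,
#' and `mu_E` is solved so the true ratio equals it.
#'
#' @param delta Reference minus placebo mean (default 9).
#' @param mu_P Placebo mean (default 16.5).
#' @param sigma_P Placebo SD (default 7.5); `sigma_E = sigma_R =
#'   sigma_P / sqrt(tau_P)`.
#' @param tau_R Variance ratio reference/experimental; must be 1 unless
#'   `allow_tau_R = TRUE`.
#' @param tau_P Variance ratio placebo/experimental (default 0.5).
#' @param n_total Total sample size, divisible by the allocation sum.
#' @param allocation Integer triple `E:R:P` (default `c(3, 2, 1)`).
#' @param xi0 Threshold (default 0.8).
#' @param xi_target True ratio for power scenarios, or `NULL` for size.
#' @param distribution `"normal"`, `"lognormal"` or `"gamma"`.
#' @param alpha Significance level (default 0.05).
#' @param reps Replications per cell (default 10000).
#' @param H GPQ draws per replication (default 5000).
#' @param B Bootstrap replicates per replication (default 1000).
#' @param seed Base seed for the cell (default 1).
#' @param allow_tau_R Permit `tau_R != 1`.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(delta = 9, mu_P = 16.5, sigma_P = 7.5,
                            tau_R = 1, tau_P = 0.5, n_total = 60,
                            allocation = c(3, 2, 1), xi0 = 0.8,
                            xi_target = NULL,
                            distribution = c("normal", "lognormal", "gamma"),
                            alpha = 0.05, reps = 10000, H = 5000, B = 1000,
                            seed = 1, allow_tau_R = FALSE) {
  distribution <- match.arg(distribution)
  if (tau_R != 1 && !allow_tau_R) {
    abort("tau_R must be 1 by design (set allow_tau_R = TRUE to override).")
  }
  if (any(allocation <= 0) || length(allocation) != 3) {
    abort("`allocation` must be three positive parts (E:R:P).")
  }
  if (n_total %% sum(allocation) != 0) {
    abort("`n_total` must be divisible by the allocation total.")
  }
  check_prob(alpha, "alpha")
  structure(list(delta = delta, mu_P = mu_P, sigma_P = sigma_P, tau_R = tau_R,
                 tau_P = tau_P, n_total = as.integer(n_total),
                 allocation = as.integer(allocation), xi0 = xi0,
                 xi_target = xi_target, distribution = distribution,
                 alpha = alpha, reps = as.integer(reps), H = as.integer(H),
                 B = as.integer(B), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Resolve a scenario into population parameters
#'
#' Maps a [scenario_config()] to [population_params()]: `mu_R = mu_P +
#' delta`, `sigma_E = sigma_R = sigma_P / sqrt(tau_P)` (scaled by
#' `sqrt(tau_R)` for the reference when overridden), group sizes from the
#' allocation, and `mu_E` either from the null construction
#' `xi0 * delta + mu_P` (size scenarios) or, for power scenarios, by
#' root-finding on the monotone map `mu_E -> theta_E` so that the true
#' ratio equals `xi_target` (tolerance 1e-10).
#'
#' @param config A [scenario_config()].
#' @return A [population_params()] object.
#' @export
resolve_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  parts <- config$allocation
  n <- config$n_total * parts / sum(parts)
  mu_R <- config$mu_P + config$delta
  sigma2_E <- config$sigma_P^2 / config$tau_P
  sigma2_R <- sigma2_E * config$tau_R
  make <- function(mu_E) population_params(
    mu_E = mu_E, mu_R = mu_R, mu_P = config$mu_P,
    sigma2_E = sigma2_E, sigma2_R = sigma2_R, sigma2_P = config$sigma_P^2,
    n_E = n[1], n_R = n[2], n_P = n[3],
    check_equal_var = config$tau_R == 1)
  if (is.null(config$xi_target)) {
    return(make(config$xi0 * config$delta + config$mu_P))
  }
  f <- function(mu_E) xi_true(make(mu_E)) - config$xi_target
  lo <- config$mu_P * 0.5
  hi <- mu_R + 5 * abs(config$delta)
  root <- tryCatch(uniroot(f, c(lo, hi), tol = 1e-10, extendInt = "upX"),
                   error = function(e) abort(
                     sprintf("configuration error: cannot solve mu_E for xi_target = %g (%s)",
                             config$xi_target, conditionMessage(e))))
  make(root$root)
}

#' Generate one three-arm data set from population parameters
#'
#' Per-arm i.i.d. draws with mean `mu_i` and variance `sigma_i^2` under the
#' requested family, by moment matching: normal `N(mu, sigma^2)`; log-normal
#' with log-mean `log(mu) - log(sigma^2/mu^2 + 1)/2` and log-variance
#' `log(sigma^2/mu^2 + 1)`; gamma with shape `mu^2/sigma^2` and scale
#' `sigma^2/mu` (non-normal families require positive means).
#'
#' @param params A [population_params()] object.
#' @param distribution `"normal"`, `"lognormal"` or `"gamma"`.
#' @return A long tibble with columns `group`, `value`.
#' @export
generate_three_arm <- function(params,
                               distribution = c("normal", "lognormal", "gamma")) {
  stopifnot(inherits(params, "population_params"))
  distribution <- match.arg(distribution)
  mu <- c(E = params$mu_E, R = params$mu_R, P = params$mu_P)
  s2 <- c(E = params$sigma2_E, R = params$sigma2_R, P = params$sigma2_P)
  n <- c(E = params$n_E, R = params$n_R, P = params$n_P)
  if (distribution != "normal" && any(mu <= 0)) {
    abort("configuration error: log-normal/gamma generation needs positive means.")
  }
  vals <- lapply(c("E", "R", "P"), function(g) {
    switch(distribution,
      normal = rnorm(n[g], mu[g], sqrt(s2[g])),
      lognormal = {
        s2l <- log(s2[g] / mu[g]^2 + 1)
        rlnorm(n[g], meanlog = log(mu[g]) - s2l / 2, sdlog = sqrt(s2l))
      },
      gamma = rgamma(n[g], shape = mu[g]^2 / s2[g], scale = s2[g] / mu[g]))
  })
  tibble::tibble(group = rep(c("E", "R", "P"), times = n),
                 value = unlist(vals))
}
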