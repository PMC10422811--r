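#' Run one simulation cell
#'
#' Simulates `reps` independent three-arm trials under a scenario and
#' applies one test per trial at `(xi0, alpha, direction = "greater")`,
#' returning the empirical rejection rate with its binomial Monte-Carlo
#' standard error. Per-replication RNG streams are derived from
#' `(seed, cell, rep)`, so results do not depend on scheduling order.
#' Replications whose test fails (degenerate data) are tallied; a cell with
#' more than 1% failures is flagged invalid.
#'
#' @param config A [scenario_config()].
#' @param method `"gpv"`, `"delta"` or `"bootstrap"`.
#' @param cell Integer cell index used in seed derivation (default 0).
#' @return A one-row tibble: scenario descriptors, `method`,
#'   `rejection_rate`, `mc_se`, `xi_true`, `n_failures`, `valid`.
#' @export
run_cell <- function(config, method = c("gpv", "delta", "bootstrap"), cell = 0L) {
  method <- match.arg(method)
  stopifnot(inherits(config, "scenario_config"))
  params <- resolve_scenario(config)
  xi <- xi_true(params)
  rej <- 0L; fail <- 0L
  for (b in seq_len(config$reps)) {
    set.seed(derive_seed(config$seed, cell, b))
    d <- generate_three_arm(params, config$distribution)
    res <- tryCatch(
      switch(method,
        gpv = gpv_test(summarize_arms(d), xi0 = config$xi0,
                       alpha = config$alpha, direction = "greater",
                       H = config$H, seed = NULL),
        delta = delta_test(summarize_arms(d), xi0 = config$xi0,
                           alpha = config$alpha, direction = "greater"),
        bootstrap = bootstrap_test(d, xi0 = config$xi0, alpha = config$alpha,
                                   direction = "greater", B = config$B,
                                   seed = NULL)),
      error = function(e) NULL)
    if (is.null(res)) fail <- fail + 1L else if (res$reject) rej <- rej + 1L
  }
  n_ok <- config$reps - fail
  rate <- if (n_ok > 0) rej / n_ok else NA_real_
  if (fail > 0.01 * config$reps) {
    warn(sprintf("cell flagged invalid: %d/%d replications failed.", fail, config$reps))
  }
  tibble::tibble(
    delta = config$delta, tau_R = config$tau_R, tau_P = config$tau_P,
    n_total = config$n_total, distribution = config$distribution,
    xi0 = config$xi0,
    xi_target = if (is.null(config$xi_target)) NA_real_ else config$xi_target,
    xi_true = xi, method = method, reps = config$reps,
    rejection_rate = rate, mc_se = sqrt(rate * (1 - rate) / max(n_ok, 1L)),
    n_failures = fail, valid = fail <= 0.01 * config$reps)
}

#' Run a grid of simulation cells
#'
#' Maps [run_cell()] over a tibble of scenario settings, one row per cell;
#' any column matching a [scenario_config()] argument overrides its default.
#' Rows are crossed with `methods`.
#'
#' @param grid A data frame of scenario settings.
#' @param methods Character vector of methods to run per cell.
#' @return A tidy tibble, one row per cell x method.
#' @export
run_scenarios <- function(grid, methods = "gpv") {
  grid <- tibble::as_tibble(grid)
  args_ok <- names(formals(scenario_config))
  purrr::list_rbind(purrr::map(seq_len(nrow(grid)), function(i) {
    row <- as.list(grid[i, , drop = FALSE])
    row <- row[!vapply(row, function(x) is.na(x)[1] && !is.list(x), TRUE)]
    cfg <- do.call(scenario_config, row[intersect(names(row), args_ok)])
    purrr::list_rbind(purrr::map(methods, function(m) run_cell(cfg, m, cell = i)))
  }))
}

#' Empirical power curve over a range of true ratios
#'
#' Convenience wrapper: for each `xi` in `xi_values`, solves the power
#' scenario (via `xi_target`) and runs the requested methods, producing a
#' tidy power table suitable for [autoplot.triarm_power()].
#'
#' @param config Base [scenario_config()] (its `xi_target` is overridden).
#' @param xi_values True effect-retention ratios to scan.
#' @param methods Methods to compare.
#' @return A tibble of class `"triarm_power"`.
#' @export
power_curve <- function(config, xi_values, methods = c("gpv", "delta", "bootstrap")) {
  stopifnot(inherits(config, "scenario_config"))
  out <- purrr::list_rbind(purrr::map(seq_along(xi_values), function(i) {
    cfg <- config
    cfg$xi_target <- xi_values[i]
    purrr::list_rbind(purrr::map(methods, function(m) run_cell(cfg, m, cell = 1000L + i)))
  }))
  class(out) <- c("triarm_power", class(out))
  out
}

#' Estimator properties of the non-inferiority limit
#'
#' For each replication, computes the point estimate of the ratio and an
#' equal-tailed two-sided 95% interval per method, then summarizes bias,
#' MSE and coverage probability of the true ratio. Point estimates: GPV uses
#' the median of the retained GPQ draws, Delta the Searls plug-in ratio,
#' bootstrap the mean of the replicate ratios. Intervals: GPV the 2.5%/97.5%
#' draw quantiles; Delta the normal interval; bootstrap the basic
#' (residual-reflected) interval.
#'
#' @param config A [scenario_config()] (size-type, `xi_target = NULL`).
#' @param methods Methods to evaluate.
#' @param level Two-sided confidence level (default 0.95).
#' @param cell Integer cell index for seed derivation.
#' @return A tibble, one row per method: `bias`, `mse`, `coverage`,
#'   `mc_se_coverage`, `n_failures`.
#' @export
estimator_properties <- function(config, methods = c("gpv", "delta", "bootstrap"),
                                 level = 0.95, cell = 0L) {
  stopifnot(inherits(config, "scenario_config"))
  check_prob(level, "level")
  params <- resolve_scenario(config)
  xi <- xi_true(params)
  a2 <- (1 - level) / 2
  est <- lapply(methods, function(m) numeric(config$reps))
  cov <- lapply(methods, function(m) logical(config$reps))
  ok <- lapply(methods, function(m) rep(TRUE, config$reps))
  names(est) <- names(cov) <- names(ok) <- methods
  for (b in seq_len(config$reps)) {
    set.seed(derive_seed(config$seed, cell, b))
    d <- generate_three_arm(params, config$distribution)
    s <- summarize_arms(d)
    for (m in methods) {
      res <- tryCatch({
        if (m == "gpv") {
          g <- gpq_draws(s, H = config$H, seed = NULL)
          r <- kept_draws(g)
          ci <- quantile_inv_ecdf(r, c(a2, 1 - a2))
          list(point = median(r), lo = ci[1], hi = ci[2])
        } else if (m == "delta") {
          dl <- delta_test(s, xi0 = config$xi0, alpha = config$alpha)
          z <- qnorm(1 - a2)
          # centre the normal interval on the Delta-method mean ratio
          ctr <- dl$moments$mean_xi1 / dl$moments$mean_xi2
          list(point = dl$xi_hat, lo = ctr - z * dl$se, hi = ctr + z * dl$se)
        } else {
          bt <- bootstrap_test(d, xi0 = config$xi0, alpha = config$alpha,
                               direction = "greater", B = config$B, seed = NULL)
          q <- quantile_inv_ecdf(bt$e_star, c(a2, 1 - a2))
          list(point = bt$xi_hat + mean(bt$e_star),
               lo = bt$xi_hat - q[2], hi = bt$xi_hat - q[1])
        }
      }, error = function(e) NULL)
      if (is.null(res)) {
        ok[[m]][b] <- FALSE
      } else {
        est[[m]][b] <- res$point
        cov[[m]][b] <- res$lo <= xi && xi <= res$hi
      }
    }
  }
  purrr::list_rbind(purrr::map(methods, function(m) {
    keep <- ok[[m]]
    e <- est[[m]][keep]; cv <- cov[[m]][keep]
    tibble::tibble(method = m, reps = sum(keep), xi_true = xi,
                   bias = mean(e - xi), mse = mean((e - xi)^2),
                   coverage = mean(cv),
                   mc_se_coverage = sqrt(mean(cv) * (1 - mean(cv)) / sum(keep)),
                   n_failures = sum(!keep))
  }))
}
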