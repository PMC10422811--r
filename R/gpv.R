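#' Monte-Carlo draws of the generalized pivotal quantity for the ratio
#'
#' Draws `H` realizations of the generalized pivotal quantity (GPQ) for the
#' effect-retention ratio `xi = (theta_E - theta_P) / (theta_R - theta_P)` on
#' Searls CV-adjusted means. Per draw, independent standard normals
#' `Z_E, Z_R, Z_P` and chi-squares `U_i ~ chisq(n_i - 1)` yield mean pivots
#' `R_mu_i = xbar_i - Z_i * sqrt((n_i - 1) s_i^2 / (n_i U_i))` and variance
#' pivots `R_sigma2_i = (n_i - 1) s_i^2 / U_i`, where the experimental and
#' reference arms both use the pooled variance in place of `s_i^2` (the
#' design assumes they share one variance). Each arm's CV-adjusted pivot is
#' `R_theta_i = n_i R_mu_i / (n_i + R_sigma2_i / R_mu_i^2)` and the ratio
#' pivot is `R_xi = (R_theta_E - R_theta_P) / (R_theta_R - R_theta_P)`.
#'
#' The denominator `theta_R - theta_P` is positive by design (the reference
#' must beat placebo for the trial to be interpretable), so draws whose
#' denominator pivot is non-positive contradict the design constraint and
#' are excluded from the retained set; they are tallied in `n_nonpos_denom`.
#' Without this conditioning the ratio indicator is severely conservative,
#' because every negative-denominator draw lands on the acceptance side
#' regardless of the evidence. Literal NaN/Inf draws are likewise dropped
#' and tallied.
#'
#' @param summaries Per-arm summary tibble (see [summarize_arms()]), or raw
#'   long data which will be summarized.
#' @param H Number of Monte-Carlo draws (default 10000).
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @return An object of class `"gpq_draws"`: list with `r_xi` (length `H`;
#'   excluded draws are `NA`), `H`, `seed`, `n_nonfinite`, `n_nonpos_denom`,
#'   `xi_hat` (plug-in estimate) and the `summaries` used.
#' @examples
#' s <- tibble::tibble(group = c("E", "R", "P"), n = c(5, 4, 7),
#'                     mean = c(3.8, 25, 2.57), sd = c(1.1, 8.91, 1.27))
#' g <- gpq_draws(s, H = 1000, seed = 1)
#' quantile(g$r_xi, 0.95, na.rm = TRUE)
#' @export
gpq_draws <- function(summaries, H = 10000, seed = NULL) {
  s <- as_arm_summaries(summaries)
  if (!is.numeric(H) || H < 1) abort("`H` must be a positive integer.")
  H <- as.integer(H)
  if (!is.null(seed)) set.seed(seed)

  e <- as.list(s[s$group == "E", ]); r <- as.list(s[s$group == "R", ])
  p <- as.list(s[s$group == "P", ])
  s2p <- pooled_var_scalar(e$n, e$var, r$n, r$var)

  Z_E <- rnorm(H); Z_R <- rnorm(H); Z_P <- rnorm(H)
  U_E <- rchisq(H, e$n - 1); U_R <- rchisq(H, r$n - 1); U_P <- rchisq(H, p$n - 1)

  Rmu_E <- e$mean - Z_E * sqrt((e$n - 1) * s2p / (e$n * U_E))
  Rmu_R <- r$mean - Z_R * sqrt((r$n - 1) * s2p / (r$n * U_R))
  Rmu_P <- p$mean - Z_P * sqrt((p$n - 1) * p$var / (p$n * U_P))
  Rs2_E <- (e$n - 1) * s2p / U_E
  Rs2_R <- (r$n - 1) * s2p / U_R
  Rs2_P <- (p$n - 1) * p$var / U_P

  Rth_E <- e$n * Rmu_E / (e$n + Rs2_E / Rmu_E^2)
  Rth_R <- r$n * Rmu_R / (r$n + Rs2_R / Rmu_R^2)
  Rth_P <- p$n * Rmu_P / (p$n + Rs2_P / Rmu_P^2)

  den <- Rth_R - Rth_P
  r_xi <- (Rth_E - Rth_P) / den

  nonfinite <- !is.finite(r_xi)
  nonpos <- is.finite(r_xi) & den <= 0
  r_xi[nonfinite | nonpos] <- NA_real_
  if (all(is.na(r_xi))) abort("inference failure: no valid GPQ draws.")

  structure(list(r_xi = r_xi, H = H, seed = seed,
                 n_nonfinite = sum(nonfinite), n_nonpos_denom = sum(nonpos),
                 xi_hat = xi_hat_from_summaries(s), summaries = s),
            class = "gpq_draws")
}

kept_draws <- function(draws) {
  stopifnot(inherits(draws, "gpq_draws"))
  draws$r_xi[!is.na(draws$r_xi)]
}

#' Generalized p-value from GPQ draws
#'
#' Estimates the generalized p-value as the indicator proportion of retained
#' draws on the null side of `xi0`: for `direction = "greater"`
#' (H1: xi > xi0) the proportion with `R_xi <= xi0` (ties inclusive); for
#' `direction = "less"` (H1: xi < xi0) the proportion with `R_xi >= xi0`.
#'
#' @param draws A [gpq_draws()] object.
#' @param xi0 Non-inferiority (or safety) threshold.
#' @param direction `"greater"` or `"less"` (the alternative hypothesis).
#' @return A p-value in `[0, 1]`.
#' @export
gpv_p_value <- function(draws, xi0, direction = c("greater", "less")) {
  direction <- check_direction(match.arg(direction))
  r <- kept_draws(draws)
  if (direction == "greater") mean(r <= xi0) else mean(r >= xi0)
}

#' Generalized confidence limit from GPQ draws
#'
#' One-sided generalized confidence limit for the effect-retention ratio:
#' the empirical `level`-quantile (side `"upper"`) or `(1 - level)`-quantile
#' (side `"lower"`) of the retained draws, under the inverse-empirical-CDF
#' (ceiling-index order statistic) quantile rule.
#'
#' @param draws A [gpq_draws()] object.
#' @param level Confidence level in (0, 1), e.g. 0.95.
#' @param side `"lower"` or `"upper"`.
#' @return The confidence limit (a single number).
#' @export
gpv_conf_limit <- function(draws, level = 0.95, side = c("lower", "upper")) {
  side <- match.arg(side)
  check_prob(level, "level")
  r <- kept_draws(draws)
  p <- if (side == "upper") level else 1 - level
  quantile_inv_ecdf(r, p)
}

# Shared result constructor for all three procedures.
new_triarm_test <- function(method, p_value, conf_limit, level, direction,
                            xi0, alpha, xi_hat, extra = list()) {
  structure(c(list(method = method, p_value = p_value, conf_limit = conf_limit,
                   level = level, direction = direction, xi0 = xi0,
                   alpha = alpha, reject = p_value < alpha, xi_hat = xi_hat),
              extra),
            class = "triarm_test")
}

#' GPV-based non-inferiority test for a three-arm trial
#'
#' The headline procedure: Monte-Carlo generalized p-value and generalized
#' confidence limit for the effect-retention ratio on Searls CV-adjusted
#' means (see [gpq_draws()] for the pivotal construction). With
#' `direction = "greater"` it tests H0: xi <= xi0 against H1: xi > xi0
#' (non-inferiority, reported with the lower confidence limit); with
#' `"less"` the reversed safety-style hypothesis, reported with the upper
#' limit.
#'
#' @param data Raw long data (`group`, `value`) or per-arm summaries
#'   (`group`, `n`, `mean`, `sd`).
#' @param xi0 Threshold for the ratio, e.g. 0.8 (non-inferiority) or 0.5
#'   (safety).
#' @param alpha One-sided significance level (default 0.05).
#' @param direction `"greater"` or `"less"` (the alternative).
#' @param H Number of GPQ draws (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @return A `"triarm_test"` object; see [tidy.triarm_test()].
#' @examples
#' s <- tibble::tibble(group = c("E", "R", "P"), n = c(5, 4, 7),
#'                     mean = c(3.8, 25, 2.57), sd = c(1.1, 8.91, 1.27))
#' gpv_test(s, xi0 = 0.5, direction = "less", H = 2000, seed = 1)
#' @export
gpv_test <- function(data, xi0 = 0.8, alpha = 0.05,
                     direction = c("greater", "less"), H = 10000, seed = NULL) {
  direction <- match.arg(direction)
  check_prob(alpha, "alpha")
  draws <- gpq_draws(data, H = H, seed = seed)
  p <- gpv_p_value(draws, xi0, direction)
  limit <- gpv_conf_limit(draws, level = 1 - alpha,
                          side = if (direction == "greater") "lower" else "upper")
  new_triarm_test("gpv", p, limit, 1 - alpha, direction, xi0, alpha,
                  draws$xi_hat,
                  extra = list(H = draws$H, seed = seed,
                               n_nonfinite = draws$n_nonfinite,
                               n_nonpos_denom = draws$n_nonpos_denom,
                               draws = draws))
}

#' @export
print.triarm_test <- function(x, ...) {
  lab <- c(gpv = "Generalized p-value (GPV) test",
           delta = "Delta-method test",
           bootstrap = "Residual-bootstrap test")[[x$method]]
  h1 <- if (x$direction == "greater") sprintf("xi > %g", x$xi0) else sprintf("xi < %g", x$xi0)
  side <- if (x$direction == "greater") "lower" else "upper"
  cat(lab, "\n")
  cat(sprintf("  H1: %s   (xi = (theta_E - theta_P)/(theta_R - theta_P), Searls-adjusted)\n", h1))
  cat(sprintf("  xi-hat = %.4f\n", x$xi_hat))
  cat(sprintf("  p-value = %.4g   one-sided %g%% %s limit = %.4f\n",
              x$p_value, 100 * x$level, side, x$conf_limit))
  cat(sprintf("  decision at alpha = %g: %s\n", x$alpha,
              if (x$reject) "reject H0" else "do not reject H0"))
  dropped <- (x$n_nonfinite %||% 0) + (x$n_nonpos_denom %||% 0)
  if (dropped > 0) {
    cat(sprintf("  [%d draw(s) excluded: %d non-finite, %d non-positive denominator]\n",
                dropped, x$n_nonfinite %||% 0, x$n_nonpos_denom %||% 0))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
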