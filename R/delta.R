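#' Approximate moments of the Searls CV-adjusted mean estimator
#'
#' First-order Taylor (Delta-method) moments of the plug-in estimator
#' `theta-hat = n Xbar / (n + S^2 / Xbar^2)` viewed as `g(Xbar, S^2)` under
#' normal sampling: `E(theta-hat) ~ g(mu, sigma^2)` and
#' `Var(theta-hat) ~ g_m^2 sigma^2/n + g_v^2 2 sigma^4/(n-1)`, using
#' `Var(Xbar) = sigma^2/n`, `Var(S^2) = 2 sigma^4/(n-1)` and
#' `Cov(Xbar, S^2) = 0`. The analytic partials of
#' `g(m, v) = n m^3 / (n m^2 + v)` are
#' `g_m = n m^2 (n m^2 + 3v) / (n m^2 + v)^2` and
#' `g_v = -n m^3 / (n m^2 + v)^2`.
#'
#' @param n Sample size.
#' @param mean Population (or plug-in) mean, nonzero.
#' @param var Population (or plug-in) variance, positive.
#' @return A named vector `c(mean = ..., var = ...)`.
#' @export
searls_moments <- function(n, mean, var) {
  if (any(mean == 0)) abort("`mean` of 0: coefficient of variation undefined.")
  m <- mean; v <- var
  nm2 <- n * m^2
  g  <- n * m^3 / (nm2 + v)
  gm <- n * m^2 * (nm2 + 3 * v) / (nm2 + v)^2
  gv <- -n * m^3 / (nm2 + v)^2
  c(mean = g, var = gm^2 * v / n + gv^2 * 2 * v^2 / (n - 1))
}

#' Delta-method non-inferiority test for a three-arm trial
#'
#' Asymptotic competitor to [gpv_test()]. With `xi1-hat = theta-hat_E -
#' theta-hat_P` and `xi2-hat = theta-hat_R - theta-hat_P` (Searls plug-ins,
#' each arm's own variance), the ratio `xi-hat = xi1-hat / xi2-hat` is
#' treated as asymptotically normal with `E(xi-hat) ~ mu1/mu2` and
#' `Var(xi-hat) ~ (mu1/mu2)^2 (V1/mu1^2 + V2/mu2^2 - 2 C/(mu1 mu2))`, where
#' the per-arm moments come from [searls_moments()] evaluated at plug-ins
#' and `C = Cov(xi1-hat, xi2-hat) = Var(theta-hat_P)` (shared placebo arm,
#' independent arms). Rejection for `direction = "greater"` requires
#' `xi-hat - z_alpha sqrt(Var) > xi0`.
#'
#' @inheritParams gpv_test
#' @return A `"triarm_test"` object.
#' @export
delta_test <- function(data, xi0 = 0.8, alpha = 0.05,
                       direction = c("greater", "less")) {
  direction <- match.arg(direction)
  check_prob(alpha, "alpha")
  s <- as_arm_summaries(data)
  mom <- lapply(seq_len(3), function(i) searls_moments(s$n[i], s$mean[i], s$var[i]))
  names(mom) <- s$group
  mu1 <- mom$E[["mean"]] - mom$P[["mean"]]
  mu2 <- mom$R[["mean"]] - mom$P[["mean"]]
  v1 <- mom$E[["var"]] + mom$P[["var"]]
  v2 <- mom$R[["var"]] + mom$P[["var"]]
  cv12 <- mom$P[["var"]]
  if (mu2 == 0) abort("inference failure: estimated theta_R - theta_P is zero.")
  xi <- mu1 / mu2
  vr <- xi^2 * (v1 / mu1^2 + v2 / mu2^2 - 2 * cv12 / (mu1 * mu2))
  if (!is.finite(vr) || vr <= 0) abort("inference failure: nonpositive Delta-method variance.")
  se <- sqrt(vr)
  z <- (xi - xi0) / se
  if (direction == "greater") {
    p <- pnorm(z, lower.tail = FALSE)
    limit <- xi - qnorm(1 - alpha) * se
  } else {
    p <- pnorm(z)
    limit <- xi + qnorm(1 - alpha) * se
  }
  new_triarm_test("delta", p, limit, 1 - alpha, direction, xi0, alpha,
                  xi_hat_from_summaries(s),
                  extra = list(se = se,
                               moments = list(mean_xi1 = mu1, var_xi1 = v1,
                                              mean_xi2 = mu2, var_xi2 = v2,
                                              cov_xi12 = cv12, var_xi_ratio = vr)))
}
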