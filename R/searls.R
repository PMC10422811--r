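#' Searls CV-adjusted mean
#'
#' The Searls adjustment shrinks a mean by its (squared) coefficient of
#' variation: `theta = n * mu / (n + sigma2 / mu^2)`. With known CV this is
#' the minimum-MSE linear estimator of the mean; here it serves as the
#' per-arm effect measure, evaluated either at population values
#' `(mu, sigma2)` or at plug-ins `(xbar, s2)` — estimand and estimator share
#' the one formula.
#'
#' @param n Sample size(s).
#' @param mean Arm mean(s); must be nonzero.
#' @param var Arm variance(s); positive.
#' @return `n * mean / (n + var / mean^2)`, vectorized over the inputs.
#'   Always no larger than `|mean|` in magnitude, and increasing towards
#'   `mean` as `n` grows.
#' @examples
#' searls_theta(7, 2.57, 1.27^2)
#' @export
searls_theta <- function(n, mean, var) {
  if (any(mean == 0)) abort("`mean` of 0: coefficient of variation undefined.")
  if (any(var < 0)) abort("`var` must be nonnegative.")
  if (any(n < 1)) abort("`n` must be a positive sample size.")
  n * mean / (n + var / mean^2)
}

#' Pooled variance of the experimental and reference arms
#'
#' Under the design assumption that the experimental and reference arms share
#' one variance, both are estimated by the pooled estimator
#' `((nE-1) sE^2 + (nR-1) sR^2) / (nE + nR - 2)`.
#'
#' @param summaries Per-arm summary tibble (see [summarize_arms()]); only the
#'   `E` and `R` rows are used.
#' @return The pooled variance (a single number).
#' @export
pooled_variance <- function(summaries) {
  s <- check_summaries(summaries)
  e <- s[s$group == "E", ]
  r <- s[s$group == "R", ]
  pooled_var_scalar(e$n, e$var, r$n, r$var)
}

pooled_var_scalar <- function(n1, v1, n2, v2) {
  ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
}

#' Population parameters of a three-arm trial
#'
#' Bundles per-arm means, variances and sample sizes. The gold-standard
#' design assumes the experimental and reference variances are equal; set
#' `check_equal_var = FALSE` to describe populations outside that design.
#'
#' @param mu_E,mu_R,mu_P Arm means (nonzero).
#' @param sigma2_E,sigma2_R,sigma2_P Arm variances (positive).
#' @param n_E,n_R,n_P Arm sample sizes (positive integers).
#' @param check_equal_var Assert `sigma2_E == sigma2_R` (default TRUE).
#' @return A list of class `"population_params"`.
#' @export
population_params <- function(mu_E, mu_R, mu_P, sigma2_E, sigma2_R, sigma2_P,
                              n_E, n_R, n_P, check_equal_var = TRUE) {
  if (any(c(mu_E, mu_R, mu_P) == 0)) abort("population means must be nonzero.")
  if (any(c(sigma2_E, sigma2_R, sigma2_P) <= 0)) abort("variances must be positive.")
  if (any(c(n_E, n_R, n_P) < 1)) abort("sample sizes must be positive.")
  if (check_equal_var && !isTRUE(all.equal(sigma2_E, sigma2_R))) {
    abort("design assumption violated: sigma2_E must equal sigma2_R (set check_equal_var = FALSE to override).")
  }
  structure(list(mu_E = mu_E, mu_R = mu_R, mu_P = mu_P,
                 sigma2_E = sigma2_E, sigma2_R = sigma2_R, sigma2_P = sigma2_P,
                 n_E = as.integer(n_E), n_R = as.integer(n_R), n_P = as.integer(n_P)),
            class = "population_params")
}

#' True effect-retention ratio of a population
#'
#' The estimand: `xi = (theta_E - theta_P) / (theta_R - theta_P)`, the
#' experimental-over-reference ratio of CV-adjusted mean gains over placebo.
#'
#' @param params A [population_params()] object.
#' @return The ratio `xi` (a single number).
#' @export
xi_true <- function(params) {
  stopifnot(inherits(params, "population_params"))
  th_E <- searls_theta(params$n_E, params$mu_E, params$sigma2_E)
  th_R <- searls_theta(params$n_R, params$mu_R, params$sigma2_R)
  th_P <- searls_theta(params$n_P, params$mu_P, params$sigma2_P)
  if (th_R == th_P) abort("theta_R equals theta_P: effect-retention ratio undefined.")
  (th_E - th_P) / (th_R - th_P)
}

# Plug-in xi-hat from an arm-summary tibble (each arm's own variance).
xi_hat_from_summaries <- function(s) {
  th <- searls_theta(s$n, s$mean, s$var)
  names(th) <- s$group
  if (th[["R"]] == th[["P"]]) abort("theta_R equals theta_P in the data: ratio undefined.")
  unname((th[["E"]] - th[["P"]]) / (th[["R"]] - th[["P"]]))
}
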