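#' Residual-bootstrap non-inferiority test for a three-arm trial
#'
#' The basic (residual) bootstrap competitor. Each replicate resamples each
#' arm independently with replacement at its own size (stratified), computes
#' the Searls plug-in ratio `xi-hat*` and the residual `e* = xi-hat* -
#' xi-hat`. For `direction = "greater"` the one-sided lower limit is
#' `xi-hat - q_{1-alpha}(e*)` and non-inferiority is claimed when it exceeds
#' `xi0`; for `"less"` the upper limit is `xi-hat - q_{alpha}(e*)` with the
#' reversed decision. The p-value is reported, by convention, as the
#' proportion of residual-centred replicates `xi-hat - e*` on the null side
#' of `xi0`. Quantiles use the shared inverse-empirical-CDF rule.
#'
#' Raw observations are required: resampling is of subjects, so summary
#' statistics alone are insufficient.
#'
#' @param data Raw long data with columns `group`, `value`.
#' @param xi0,alpha,direction As in [gpv_test()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed.
#' @return A `"triarm_test"` object with the replicate residuals in `e_star`.
#' @export
bootstrap_test <- function(data, xi0 = 0.8, alpha = 0.05,
                           direction = c("greater", "less"), B = 1000,
                           seed = NULL) {
  direction <- match.arg(direction)
  check_prob(alpha, "alpha")
  if (!is.numeric(B) || B < 1) abort("`B` must be a positive integer.")
  B <- as.integer(B)
  if (!is.data.frame(data) || !"value" %in% names(data)) {
    abort("bootstrap_test needs raw per-subject data (columns `group`, `value`); summary statistics are not resampleable.")
  }
  raw <- check_raw_data(data)
  s <- summarize_arms(raw)
  xi_hat <- xi_hat_from_summaries(s)
  if (!is.null(seed)) set.seed(seed)

  xs <- split(raw$value, raw$group)[c("E", "R", "P")]
  xi_star <- replicate_xi_star(xs, B)

  nonfinite <- !is.finite(xi_star)
  e_star <- xi_star[!nonfinite] - xi_hat
  if (length(e_star) == 0) abort("inference failure: all bootstrap replicates degenerate.")

  if (direction == "greater") {
    limit <- xi_hat - quantile_inv_ecdf(e_star, 1 - alpha)
    reject <- limit > xi0
    p <- mean(xi_hat - e_star <= xi0)
  } else {
    limit <- xi_hat - quantile_inv_ecdf(e_star, alpha)
    reject <- limit < xi0
    p <- mean(xi_hat - e_star >= xi0)
  }
  out <- new_triarm_test("bootstrap", p, limit, 1 - alpha, direction, xi0,
                         alpha, xi_hat,
                         extra = list(B = B, seed = seed,
                                      n_nonfinite = sum(nonfinite),
                                      e_star = e_star))
  # decision follows the quantile limit rule, not p < alpha
  out$reject <- reject
  out
}

# Vectorized stratified resampling: per arm an n x B index matrix, column
# means and column variances, then the Searls plug-in ratio per replicate.
replicate_xi_star <- function(xs, B) {
  stat <- lapply(xs, function(x) {
    n <- length(x)
    m <- matrix(x[sample.int(n, n * B, replace = TRUE)], nrow = n)
    mu <- colMeans(m)
    v <- (colSums(m^2) - n * mu^2) / (n - 1)
    list(n = n, mu = mu, v = v)
  })
  th <- lapply(stat, function(a) {
    v <- pmax(a$v, 0)  # guard tiny negative rounding; constant resample => theta = mean
    out <- a$n * a$mu / (a$n + v / a$mu^2)
    out[a$mu == 0] <- NA_real_
    out
  })
  out <- (th$E - th$P) / (th$R - th$P)
  out[is.finite(out) & th$R == th$P] <- NA_real_
  out
}
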