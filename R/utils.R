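#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm rchisq rlnorm rgamma var sd pnorm qnorm uniroot median quantile
NULL

# Inverse-empirical-CDF (order-statistic, ceiling-index) quantile. One rule,
# shared by the GPV and bootstrap machinery, so that confidence limits have the
# same 1/H granularity as the indicator-based p-value estimator.
quantile_inv_ecdf <- function(x, probs) {
  stopifnot(all(probs >= 0 & probs <= 1))
  x <- sort(x)
  n <- length(x)
  idx <- pmin(pmax(ceiling(n * probs - 1e-9), 1L), n)  # guard FP noise in n*p
  x[idx]
}

# Deterministic stream seed for (seed, cell, rep). Exact integer arithmetic in
# doubles (all terms < 2^53); result in [1, 2^31 - 78] fits set.seed().
derive_seed <- function(seed, cell = 0L, rep = 0L) {
  h <- (as.numeric(seed) * 48271 + as.numeric(cell) * 16807 +
          as.numeric(rep) * 69621) %% 2147483570
  as.integer(h) + 1L
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1) {
    abort(sprintf("`%s` must be a single number strictly between 0 and 1.", name))
  }
  invisible(x)
}

check_direction <- function(direction) {
  if (!is.character(direction) || !direction[1L] %in% c("greater", "less")) {
    abort('`direction` must be "greater" (H1: xi > xi0) or "less" (H1: xi < xi0).')
  }
  direction[1L]
}
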