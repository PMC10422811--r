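# Shared fixtures, built in code.

# Mutagenicity assay summaries: one dose arm (E) vs positive control (R)
# and vehicle control (P).
mutagenicity_arms <- function(dose = c("30", "50", "75", "100")) {
  dose <- match.arg(dose)
  d <- list(`30` = c(5, 3.80, 1.10), `50` = c(5, 6.20, 1.48),
            `75` = c(5, 14.0, 3.94), `100` = c(5, 20.0, 4.06))[[dose]]
  tibble::tibble(group = c("E", "R", "P"),
                 n = c(d[1], 4, 7),
                 mean = c(d[2], 25.0, 2.57),
                 sd = c(d[3], 8.91, 1.27))
}

# Wrap a plain numeric vector of pivotal draws as a gpq_draws object.
fake_draws <- function(r) structure(list(r_xi = r, H = length(r)), class = "gpq_draws")

# Small raw three-arm data set (normal), deterministic.
small_raw <- function(seed = 42, n = c(12, 10, 8), mu = c(20, 22, 15), sd = c(4, 4, 3)) {
  set.seed(seed)
  tibble::tibble(
    group = rep(c("E", "R", "P"), times = n),
    value = c(rnorm(n[1], mu[1], sd[1]), rnorm(n[2], mu[2], sd[2]),
              rnorm(n[3], mu[3], sd[3])))
}

# Exact (enumerated) bootstrap distribution of xi-hat* for arms of size 2:
# per arm the 4 ordered resamples are equally likely; enumerate all 64 joint
# outcomes. Returns the 64 equally-likely xi-hat* values.
enumerate_xi_star_n2 <- function(xE, xR, xP) {
  pairs <- function(x) list(c(x[1], x[1]), c(x[1], x[2]), c(x[2], x[1]), c(x[2], x[2]))
  th <- function(x) {
    n <- 2; m <- mean(x); v <- var(x)
    n * m / (n + v / m^2)
  }
  out <- numeric(0)
  for (e in pairs(xE)) for (r in pairs(xR)) for (p in pairs(xP)) {
    out <- c(out, (th(e) - th(p)) / (th(r) - th(p)))
  }
  out
}
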