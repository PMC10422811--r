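#' Summarize per-arm observations into sufficient statistics
#'
#' Reduces raw long-format trial data to the per-arm sufficient statistics
#' `(n, mean, var)` used by every test in the package. Arms are labelled
#' `E` (experimental), `R` (reference / active control) and `P` (placebo).
#'
#' @param data A data frame with columns `group` (values among `"E"`, `"R"`,
#'   `"P"`) and `value` (numeric trial outcome).
#' @return A tibble with one row per arm and columns `group`, `n`, `mean`,
#'   `sd`, `var` (unbiased, divisor `n - 1`).
#' @examples
#' d <- tibble::tibble(group = rep(c("E", "R", "P"), each = 4),
#'                     value = rnorm(12, 10))
#' summarize_arms(d)
#' @export
summarize_arms <- function(data) {
  data <- check_raw_data(data)
  xs <- split(data$value, data$group)[c("E", "R", "P")]
  out <- tibble::tibble(
    group = names(xs),
    n = unname(vapply(xs, length, 1L)),
    mean = unname(vapply(xs, mean, 1)),
    var = unname(vapply(xs, stats::var, 1)))
  out$sd <- sqrt(out$var)
  check_summaries(out[, c("group", "n", "mean", "sd", "var")])
}

# Validate raw long-format data: three arms E/R/P, each with >= 2
# non-degenerate observations.
check_raw_data <- function(data) {
  if (!is.data.frame(data) || !all(c("group", "value") %in% names(data))) {
    abort("raw data must be a data frame with columns `group` and `value`.")
  }
  data$group <- as.character(data$group)
  bad <- setdiff(unique(data$group), c("E", "R", "P"))
  if (length(bad) > 0) {
    abort(sprintf("unknown group label(s): %s (expected E, R, P).",
                  paste(bad, collapse = ", ")))
  }
  missing <- setdiff(c("E", "R", "P"), unique(data$group))
  if (length(missing) > 0) {
    abort(sprintf("missing arm(s): %s.", paste(missing, collapse = ", ")))
  }
  if (!is.numeric(data$value) || anyNA(data$value)) {
    abort("`value` must be numeric with no missing values.")
  }
  counts <- table(data$group)
  if (any(counts < 2)) {
    abort("each arm needs at least 2 observations.")
  }
  spread <- tapply(data$value, data$group, function(v) stats::var(v))
  if (any(spread <= 0)) {
    abort("degenerate sample: an arm has constant observations (zero variance).")
  }
  tibble::as_tibble(data[, c("group", "value")])
}

# Validate an arm-summary table (group, n, mean, sd and/or var).
check_summaries <- function(s) {
  if (!is.data.frame(s) || !all(c("group", "n", "mean") %in% names(s))) {
    abort("summaries must be a data frame with columns `group`, `n`, `mean` and `sd` or `var`.")
  }
  s$group <- as.character(s$group)
  if (!"var" %in% names(s)) {
    if (!"sd" %in% names(s)) abort("summaries need an `sd` or `var` column.")
    s$var <- s$sd^2
  }
  if (!"sd" %in% names(s)) s$sd <- sqrt(s$var)
  if (!setequal(s$group, c("E", "R", "P")) || nrow(s) != 3L) {
    abort("summaries must contain exactly one row per arm E, R, P.")
  }
  if (any(s$n < 2)) abort("each arm needs n >= 2.")
  if (any(s$var <= 0)) abort("arm variances must be positive.")
  if (any(s$mean == 0)) {
    abort("arm mean of 0: the coefficient of variation (and hence the CV-adjusted mean) is undefined.")
  }
  tibble::as_tibble(s[match(c("E", "R", "P"), s$group), c("group", "n", "mean", "sd", "var")])
}

# Accept either raw long data or an arm-summary table; return validated summaries.
# Attaches the raw data (if any) as an attribute for methods that need it.
as_arm_summaries <- function(data) {
  if (is.data.frame(data) && "value" %in% names(data)) {
    raw <- check_raw_data(data)
    s <- summarize_arms(raw)
    attr(s, "raw") <- raw
    s
  } else {
    check_summaries(data)
  }
}

#' Read three-arm trial data from a delimited file
#'
#' Reads either raw per-subject observations (`mode = "raw"`: columns
#' `group`, `value`) or per-arm summary statistics (`mode = "summary"`:
#' columns `group`, `n`, `mean`, `sd`), with arms labelled `E`, `R`, `P`.
#'
#' @param path Path to a CSV file.
#' @param mode `"raw"` or `"summary"`.
#' @return For `"raw"`, a tibble of observations; for `"summary"`, a
#'   validated per-arm summary tibble.
#' @export
read_arm_data <- function(path, mode = c("raw", "summary")) {
  mode <- match.arg(mode)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (mode == "raw") check_raw_data(d) else check_summaries(d)
}
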