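#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a three-arm test result
#'
#' One row per test: method, estimate, p-value, one-sided confidence limit
#' and decision.
#'
#' @param x A `"triarm_test"` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy triarm_test
#' @export
tidy.triarm_test <- function(x, ...) {
  tibble::tibble(method = x$method, xi_hat = x$xi_hat, xi0 = x$xi0,
                 direction = x$direction, p_value = x$p_value,
                 conf_limit = x$conf_limit, level = x$level,
                 reject = x$reject)
}

#' Glance at a three-arm test result
#'
#' @param x A `"triarm_test"` object.
#' @param ... Unused.
#' @return A one-row tibble with the settings echo (alpha, Monte-Carlo
#'   sizes, seed, excluded-draw tallies) sufficient to re-run the test
#'   bit-identically.
#' @method glance triarm_test
#' @export
glance.triarm_test <- function(x, ...) {
  tibble::tibble(method = x$method, alpha = x$alpha,
                 H = x$H %||% NA_integer_, B = x$B %||% NA_integer_,
                 seed = x$seed %||% NA_integer_,
                 n_nonfinite = x$n_nonfinite %||% 0L,
                 n_nonpos_denom = x$n_nonpos_denom %||% 0L,
                 p_value = x$p_value, reject = x$reject)
}

#' Plot the GPQ draw distribution of a GPV test
#'
#' Histogram of the retained pivotal draws with the threshold and the
#' one-sided confidence limit marked.
#'
#' @param object A `"triarm_test"` object from [gpv_test()].
#' @param bins Histogram bins (default 60).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triarm_test
#' @export
autoplot.triarm_test <- function(object, bins = 60, ...) {
  if (is.null(object$draws)) {
    abort("autoplot needs a GPV test result carrying its draws.")
  }
  df <- tibble::tibble(r_xi = kept_draws(object$draws))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_xi)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$xi0, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$conf_limit, colour = "red") +
    ggplot2::labs(x = expression(R[xi]), y = "draws",
                  title = sprintf("GPQ distribution (p = %.4g)", object$p_value),
                  subtitle = sprintf("dashed: xi0 = %g; red: %g%% %s limit",
                                     object$xi0, 100 * object$level,
                                     if (object$direction == "greater") "lower" else "upper"))
}

#' Plot empirical power curves
#'
#' @param object A `"triarm_power"` tibble from [power_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot triarm_power
#' @export
autoplot.triarm_power <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$xi_true, y = .data$rejection_rate,
                               colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = unique(object$xi0 * 0 + 0.05), linetype = 3) +
    ggplot2::labs(x = expression(xi), y = "empirical power",
                  colour = "method")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
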