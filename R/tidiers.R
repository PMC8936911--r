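#' Tidy an `f1_ci` object
#'
#' @param x an [f1_ci()] object.
#' @param ... unused.
#' @return a tibble with broom-standard columns `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.f1_ci <- function(x, ...) {
  est <- x$estimates
  tibble::tibble(term = est$measure,
                 estimate = est$estimate,
                 std.error = est$se,
                 conf.low = est$ci_lower,
                 conf.high = est$ci_upper)
}

#' Glance at an `f1_ci` object
#'
#' @param x an [f1_ci()] object.
#' @param ... unused.
#' @return a one-row tibble: `nobs`, `n_classes`, `alpha`, `z`, `n_measures`,
#'   `clipped`.
#' @export
glance.f1_ci <- function(x, ...) {
  tibble::tibble(nobs = x$n,
                 n_classes = x$r,
                 alpha = x$alpha,
                 z = qnorm(1 - x$alpha / 2),
                 n_measures = nrow(x$estimates),
                 clipped = any(x$estimates$clipped))
}

#' Plot F1 estimates with their Wald intervals
#'
#' @param object an [f1_ci()] object.
#' @param ... unused.
#' @return a ggplot: one point and error bar per measure.
#' @export
autoplot.f1_ci <- function(object, ...) {
  est <- object$estimates
  ggplot2::ggplot(est, ggplot2::aes(x = .data$measure, y = .data$estimate)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper),
      width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = NULL, y = "score",
      title = sprintf("F1 measures with %g%% Wald intervals (n = %d)",
                      100 * (1 - object$alpha), object$n)) +
    ggplot2::theme_minimal()
}

#' Plot empirical coverage against sample size
#'
#' @param object an `f1_coverage` tibble from [coverage_study()] or
#'   [coverage_table()]`(wide = FALSE)`.
#' @param ... unused.
#' @return a ggplot: coverage vs n (log scale) by measure, one panel per
#'   scenario, with the nominal level as a dashed line.
#' @export
autoplot.f1_coverage <- function(object, ...) {
  nominal <- 1 - object$alpha[1]
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n, y = .data$coverage,
                               colour = .data$measure)) +
    ggplot2::geom_hline(yintercept = nominal, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "sample size n", y = "empirical coverage",
                  title = sprintf("Coverage of %g%% Wald intervals",
                                  100 * nominal)) +
    ggplot2::theme_minimal()
}
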