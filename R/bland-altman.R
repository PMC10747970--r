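#' Bland-Altman agreement analysis
#'
#' Computes the bias (mean of per-subject differences
#' `d = reference - test`), its t-based confidence interval
#' `bias +/- t_(1-alpha/2, n-1) * sd(d) / sqrt(n)`, and the limits of
#' agreement `bias +/- loa_multiplier * sd(d)` (sample SD, n - 1
#' denominator). Trend diagnostics ([ba_trend()]) are attached when the
#' pair means vary: a proportional trend (differences drifting linearly
#' with magnitude) and heteroscedasticity (difference spread growing with
#' magnitude, the fan shape).
#'
#' When every difference is identical the result is still returned, with
#' the limits of agreement collapsed onto the bias and the trend flagged
#' undefined.
#'
#' @param data A data frame with `reference` and `test` columns.
#' @param alpha Significance level for the bias confidence interval and the
#'   trend diagnostics (default 0.05).
#' @param loa_multiplier Half-width of the limits of agreement in SD units
#'   (default 1.96, covering about 95% of differences under normality).
#' @return An object of class `ba_fit` with `bias`, `sd_diff`, `bias_ci`,
#'   `loa`, `n` and `trend`.
#' @examples
#' d <- data.frame(reference = c(5, 6, 7, 8, 9), test = c(4, 4, 4, 4, 4))
#' ba_fit(d)
#' @export
ba_fit <- function(data, alpha = 0.05, loa_multiplier = 1.96) {
  check_alpha(alpha)
  if (!is.numeric(loa_multiplier) || loa_multiplier <= 0) {
    abort("`loa_multiplier` must be a positive number.",
          class = "gaitagree_error_config")
  }
  pv <- paired_values(data, min_n = 3L)
  d <- pv$reference - pv$test
  means <- (pv$reference + pv$test) / 2
  n <- pv$n
  bias <- mean(d)
  sd_diff <- sd(d)
  se <- sd_diff / sqrt(n)
  bias_ci <- bias + c(-1, 1) * qt(1 - alpha / 2, df = n - 1) * se
  loa <- bias + c(-1, 1) * loa_multiplier * sd_diff

  trend <- if (sd_diff == 0 || diff(range(means)) == 0 || n < 4L) {
    list(slope_of_diff_on_mean = NA_real_, trend_p = NA_real_,
         proportional_trend = FALSE, hetero_p = NA_real_,
         heteroscedastic = FALSE, undefined = TRUE)
  } else {
    ba_trend(d, means, alpha = alpha)
  }

  structure(
    list(bias = bias, sd_diff = sd_diff, bias_ci = bias_ci, loa = loa,
         loa_multiplier = loa_multiplier, n = n, alpha = alpha,
         trend = trend, differences = d, means = means),
    class = "ba_fit")
}

#' Bland-Altman trend diagnostics
#'
#' Detects the two classic departures visible in a Bland-Altman plot: a
#' proportional systematic error (the differences regress linearly on the
#' pair means; ordinary least squares slope with its two-sided p-value) and
#' heteroscedasticity (the absolute deviations from the bias rank-correlate
#' with the pair means; Spearman test). These are diagnostics only and do
#' not enter the agreement classification.
#'
#' @param d Numeric vector of differences (reference - test).
#' @param means Numeric vector of pair means, aligned with `d`.
#' @param alpha Significance level for the flags (default 0.05).
#' @return A list with the OLS slope, both p-values and both flags.
#' @export
ba_trend <- function(d, means, alpha = 0.05) {
  check_alpha(alpha)
  if (length(d) != length(means) || length(d) < 4L) {
    abort("Trend diagnostics need aligned vectors with n >= 4.",
          class = "gaitagree_error_degenerate")
  }
  if (diff(range(means)) == 0) {
    abort("Trend diagnostics are undefined for constant pair means.",
          class = "gaitagree_error_degenerate")
  }
  ols <- lm(d ~ means)
  sm <- suppressWarnings(summary(ols))$coefficients
  slope <- unname(coef(ols)[2])
  trend_p <- if (nrow(sm) >= 2L) sm[2, 4] else NA_real_
  abs_dev <- abs(d - mean(d))
  het <- suppressWarnings(cor.test(abs_dev, means, method = "spearman"))
  list(slope_of_diff_on_mean = slope, trend_p = trend_p,
       proportional_trend = isTRUE(trend_p < alpha),
       hetero_p = het$p.value,
       heteroscedastic = isTRUE(het$p.value < alpha),
       undefined = FALSE)
}

#' @export
print.ba_fit <- function(x, ...) {
  cat(sprintf("Bland-Altman analysis (n = %d, reference - test)\n", x$n))
  cat(sprintf("  bias = %.4f  [%.4f, %.4f]\n", x$bias, x$bias_ci[1], x$bias_ci[2]))
  cat(sprintf("  limits of agreement (bias +/- %g SD): [%.4f, %.4f]\n",
              x$loa_multiplier, x$loa[1], x$loa[2]))
  if (isTRUE(x$trend$undefined)) {
    cat("  trend diagnostics undefined\n")
  } else {
    cat(sprintf("  proportional trend p = %.3g%s; heteroscedasticity p = %.3g%s\n",
                x$trend$trend_p, if (x$trend$proportional_trend) " *" else "",
                x$trend$hetero_p, if (x$trend$heteroscedastic) " *" else ""))
  }
  invisible(x)
}

#' @rdname ba_fit
#' @param x A `ba_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ba_fit <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         conf_low = x$bias_ci[1], conf_high = x$bias_ci[2],
         loa_low = x$loa[1], loa_high = x$loa[2], n = x$n)
}

#' @rdname ba_fit
#' @exportS3Method generics::glance
glance.ba_fit <- function(x, ...) {
  tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
         loa_multiplier = x$loa_multiplier,
         proportional_trend = x$trend$proportional_trend,
         heteroscedastic = x$trend$heteroscedastic)
}

#' Plot data for a Bland-Altman fit
#'
#' Returns the (pair mean, difference) points together with the bias and
#' limits-of-agreement reference lines as tibbles for external re-plotting.
#'
#' @param fit A `ba_fit` object.
#' @return A list of tibbles: `points` and `lines`.
#' @export
ba_plot_data <- function(fit) {
  stopifnot(inherits(fit, "ba_fit"))
  list(
    points = tibble(mean = fit$means, difference = fit$differences),
    lines = tibble(line = c("bias", "loa_lower", "loa_upper"),
                   value = c(fit$bias, fit$loa[1], fit$loa[2]))
  )
}

#' @rdname ba_fit
#' @param object A `ba_fit` object.
#' @exportS3Method ggplot2::autoplot
autoplot.ba_fit <- function(object, ...) {
  pd <- ba_plot_data(object)
  ggplot2::ggplot(pd$points, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = object$bias, colour = "#b2182b") +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed",
                        colour = "#b2182b") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = "Bland-Altman plot",
      subtitle = sprintf("bias = %.2f, limits of agreement [%.2f, %.2f]",
                         object$bias, object$loa[1], object$loa[2]),
      x = "mean of the two systems", y = "difference (reference - test)") +
    ggplot2::theme_minimal()
}
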