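#' All pairwise slopes for Passing-Bablok regression
#'
#' Computes the slopes `S_ij = (test_j - test_i) / (ref_j - ref_i)` over all
#' pairs i < j, with the exclusions of Passing and Bablok's Procedure I:
#' pairs with identical (reference, test) coordinates contribute nothing;
#' pairs with equal reference but different test values contribute a signed
#' infinity (ordered at the extremes, never averaged); slopes exactly equal
#' to -1 are excluded. `K`, the number of slopes below -1, is the offset of
#' the shifted median.
#'
#' @param data A data frame with `reference` and `test` columns.
#' @return A list with `slopes` (sorted ascending), `K`, `N` (number of
#'   retained slopes) and `n` (number of pairs).
#' @examples
#' pb_slopes(data.frame(reference = c(1, 2, 3), test = c(1, 2, 3)))
#' @export
pb_slopes <- function(data) {
  pv <- paired_values(data, min_n = 3L)
  x <- pv$reference
  y <- pv$test
  if (length(unique(x)) < 2L) {
    abort("Passing-Bablok needs at least 2 distinct reference values.",
          class = "gaitagree_error_degenerate")
  }
  idx <- combn(pv$n, 2L)
  dx <- x[idx[2L, ]] - x[idx[1L, ]]
  dy <- y[idx[2L, ]] - y[idx[1L, ]]
  both_zero <- dx == 0 & dy == 0
  s <- ifelse(dx == 0, sign(dy) * Inf, dy / dx)
  s <- s[!both_zero & s != -1]
  if (sum(is.finite(s)) < 3L) {
    abort("Fewer than 3 finite pairwise slopes; Passing-Bablok fit is degenerate.",
          class = "gaitagree_error_degenerate")
  }
  s <- sort(s)    # -Inf first, +Inf last
  list(slopes = s, K = sum(s < -1), N = length(s), n = pv$n)
}

# shifted order statistic with bounds checking
.pb_order_stat <- function(slopes, i) {
  if (i < 1L || i > length(slopes)) {
    abort("Requested order statistic outside the slope list.",
          class = "gaitagree_error_ci_undefined")
  }
  slopes[i]
}

#' Passing-Bablok regression
#'
#' Fits the non-parametric structural regression of the test system on the
#' reference system (Passing and Bablok's Procedure I). The slope `m` is the
#' K-shifted median of all valid pairwise slopes, where K counts slopes
#' below -1; this makes the estimate invariant under interchange of the two
#' measurement axes. The slope confidence interval is rank-based:
#' with `C = z_(1-alpha/2) * sqrt(n (n-1) (2n+5) / 18)`,
#' `M1 = round((N - C)/2)` (half away from zero) and `M2 = N - M1 + 1`, the
#' bounds are the (M1+K)-th and (M2+K)-th ordered slopes. The intercept is
#' `q = median(test - m * reference)` with bounds obtained by plugging the
#' slope bounds in (upper slope bound gives the lower intercept bound and
#' vice versa). A cusum linearity check of the residual signs is attached:
#' Passing-Bablok assumes a linear structural relationship, and the check
#' flags data that violate it.
#'
#' An interval endpoint that would be infinite (a central order statistic
#' from a tied-reference pair) raises a degenerate-fit error; a sample too
#' small for the requested level raises a CI-undefined error that carries
#' the point estimates in its condition data.
#'
#' @param data A data frame with `reference` and `test` columns.
#' @param alpha Significance level for the 1 - alpha confidence intervals
#'   (default 0.05).
#' @return An object of class `pb_fit` with slope/intercept estimates,
#'   their confidence intervals, `N`, `K`, `n` and a `linearity` element.
#' @examples
#' d <- data.frame(reference = 1:10, test = 2.1 * (1:10) - 0.06)
#' pb_fit(d)
#' @export
pb_fit <- function(data, alpha = 0.05) {
  check_alpha(alpha)
  sl <- pb_slopes(data)
  s <- sl$slopes
  N <- sl$N
  K <- sl$K
  n <- sl$n

  if (N %% 2L == 1L) {
    m <- .pb_order_stat(s, (N + 1L) %/% 2L + K)
  } else {
    m <- mean(c(.pb_order_stat(s, N %/% 2L + K),
                .pb_order_stat(s, N %/% 2L + 1L + K)))
  }
  if (!is.finite(m)) {
    abort("Central pairwise slope is infinite; fit is degenerate.",
          class = "gaitagree_error_degenerate")
  }

  C <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- as.integer(round_half_away((N - C) / 2))
  M2 <- N - M1 + 1L
  if (M1 + K < 1L || M2 + K > N) {
    abort("Sample too small for a Passing-Bablok confidence interval at this level.",
          class = "gaitagree_error_ci_undefined",
          estimates = list(m = m, q = median(data$test - m * data$reference)))
  }
  lb_m <- .pb_order_stat(s, M1 + K)
  ub_m <- .pb_order_stat(s, M2 + K)
  if (!is.finite(lb_m) || !is.finite(ub_m)) {
    abort("Slope confidence bound is infinite; fit is degenerate.",
          class = "gaitagree_error_degenerate")
  }

  pv <- paired_values(data)
  x <- pv$reference
  y <- pv$test
  q <- median(y - m * x)
  q_ci <- c(median(y - ub_m * x), median(y - lb_m * x))

  fit <- structure(
    list(m = m, m_ci = c(lb_m, ub_m), q = q, q_ci = q_ci,
         n = n, N = N, K = K, alpha = alpha,
         reference = x, test = y),
    class = "pb_fit")
  fit$linearity <- cusum_linearity(data, fit)
  fit
}

#' Cusum linearity check for a Passing-Bablok fit
#'
#' Tests the linearity assumption by walking the signs of the fit residuals
#' in order of increasing reference value (ties broken by test value): with
#' scores +1 / -1 for positive / negative residuals (zeros dropped) and L
#' nonzero scores, the statistic is `H = max_j |cumsum of scores| / sqrt(L)`.
#' A systematic curvature makes the residual signs run, inflating H; the
#' Kolmogorov-Smirnov critical value (1.36 at alpha = 0.05) bounds H under
#' linearity. A perfect fit (L = 0) yields H = 0.
#'
#' @param data A data frame with `reference` and `test` columns.
#' @param fit A `pb_fit` object (or any list with `m` and `q`).
#' @param alpha Significance level for the critical value (default 0.05).
#' @return A list with `H`, `critical_value` and `linear`.
#' @export
cusum_linearity <- function(data, fit, alpha = 0.05) {
  check_alpha(alpha)
  pv <- paired_values(data)
  ord <- order(pv$reference, pv$test)
  x <- pv$reference[ord]
  y <- pv$test[ord]
  r <- y - (fit$q + fit$m * x)
  # residuals within floating-point noise of zero carry no sign information
  tol <- 1e-8 * max(abs(y), 1)
  r[abs(r) < tol] <- 0
  scores <- sign(r)[sign(r) != 0]
  critical <- sqrt(-0.5 * log(alpha / 2))   # 1.358 at alpha = 0.05
  if (length(scores) == 0L) {
    return(list(H = 0, critical_value = critical, linear = TRUE))
  }
  H <- max(abs(cumsum(scores))) / sqrt(length(scores))
  list(H = H, critical_value = critical, linear = H <= critical)
}

#' @export
print.pb_fit <- function(x, ...) {
  cat(sprintf("Passing-Bablok regression (n = %d pairs, %d slopes, K = %d)\n",
              x$n, x$N, x$K))
  cat(sprintf("  slope     m = %.4f  [%.4f, %.4f]\n", x$m, x$m_ci[1], x$m_ci[2]))
  cat(sprintf("  intercept q = %.4f  [%.4f, %.4f]\n", x$q, x$q_ci[1], x$q_ci[2]))
  cat(sprintf("  linearity: H = %.3f (critical %.3f) -> %s\n",
              x$linearity$H, x$linearity$critical_value,
              if (x$linearity$linear) "linear" else "NOT linear"))
  invisible(x)
}

#' @rdname pb_fit
#' @param x A `pb_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pb_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$m, x$q),
         conf_low = c(x$m_ci[1], x$q_ci[1]),
         conf_high = c(x$m_ci[2], x$q_ci[2]))
}

#' @rdname pb_fit
#' @exportS3Method generics::glance
glance.pb_fit <- function(x, ...) {
  tibble(n = x$n, N = x$N, K = x$K, m = x$m, q = x$q,
         cusum_H = x$linearity$H, linear = x$linearity$linear,
         alpha = x$alpha)
}

#' Plot data for a Passing-Bablok fit
#'
#' Returns the elements of the classic method-comparison scatter plot
#' (points sorted by reference value, the fitted line, and the identity
#' line) as plain tibbles, for external re-plotting.
#'
#' @param fit A `pb_fit` object.
#' @return A list of tibbles: `points` and `lines` (fit and identity,
#'   as intercept/slope rows).
#' @export
pb_plot_data <- function(fit) {
  stopifnot(inherits(fit, "pb_fit"))
  ord <- order(fit$reference, fit$test)
  list(
    points = tibble(reference = fit$reference[ord], test = fit$test[ord]),
    lines = tibble(line = c("passing_bablok", "identity"),
                   intercept = c(fit$q, 0), slope = c(fit$m, 1))
  )
}

#' @rdname pb_fit
#' @param object A `pb_fit` object.
#' @exportS3Method ggplot2::autoplot
autoplot.pb_fit <- function(object, ...) {
  pd <- pb_plot_data(object)
  ggplot2::ggplot(pd$points, ggplot2::aes(x = .data$reference, y = .data$test)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_abline(intercept = object$q, slope = object$m,
                         colour = "#2166ac") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = "Passing-Bablok regression",
      subtitle = sprintf("m = %.2f [%.2f, %.2f], q = %.2f [%.2f, %.2f]",
                         object$m, object$m_ci[1], object$m_ci[2],
                         object$q, object$q_ci[1], object$q_ci[2]),
      x = "reference system", y = "test system") +
    ggplot2::theme_minimal()
}
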