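#' Shapiro-Wilk normality check
#'
#' Thin, validated wrapper around [stats::shapiro.test()] used as the gate
#' of the paired-comparison stage.
#'
#' @param values Numeric vector, 3 <= n <= 5000, not all identical.
#' @return A list with `W`, `p_value` and `n`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) {
    abort("Shapiro-Wilk requires 3 <= n <= 5000.",
          class = "gaitagree_error_degenerate")
  }
  if (diff(range(values)) == 0) {
    abort("Shapiro-Wilk is undefined for constant input.",
          class = "gaitagree_error_degenerate")
  }
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = n)
}

#' Normality-gated two-tailed paired comparison
#'
#' Compares the two systems on the per-subject differences
#' `d = reference - test`. Normality of `d` is assessed with the
#' Shapiro-Wilk test; if its p-value is at least `alpha` a two-tailed paired
#' t-test is run, otherwise a two-tailed Wilcoxon signed-rank test (zeros
#' dropped; exact null distribution for small tie-free samples, normal
#' approximation with continuity correction otherwise, as in
#' [stats::wilcox.test()]).
#'
#' If every difference is zero the comparison degenerates: the result is
#' flagged (`no_difference = TRUE`) with statistic 0 and p-value 1.
#'
#' @param data A data frame with `reference` and `test` columns (one row per
#'   subject), e.g. one parameter's slice of [average_trials()] output.
#' @param alpha Significance level in (0, 1) used both by the normality gate
#'   and the significance flag. Default 0.05.
#' @return An object of class `gait_paired_test`: method, statistic,
#'   p-value, significance flag and the gate's normality result.
#' @examples
#' cfg <- synthetic_config(q = 5, seed = 7)
#' paired <- average_trials(generate_gait(cfg))
#' paired_compare(dplyr::filter(paired, parameter == "cadence"))
#' @export
paired_compare <- function(data, alpha = 0.05) {
  check_alpha(alpha)
  pv <- paired_values(data, min_n = 3L)
  d <- pv$reference - pv$test
  n <- pv$n

  if (diff(range(d)) == 0) {
    if (d[1] == 0) {
      res <- list(method = "wilcoxon", statistic = 0, p_value = 1,
                  significant = FALSE, no_difference = TRUE,
                  normality = list(W = NA_real_, p_value = NA_real_, n = n))
    } else {
      # constant nonzero shift: normality undefined, fall back to Wilcoxon
      wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))
      res <- list(method = "wilcoxon", statistic = unname(wt$statistic),
                  p_value = wt$p.value, significant = wt$p.value < alpha,
                  no_difference = FALSE,
                  normality = list(W = NA_real_, p_value = NA_real_, n = n))
    }
  } else {
    sw <- shapiro_wilk(d)
    if (sw$p_value >= alpha) {
      tt <- t.test(d, mu = 0, alternative = "two.sided")
      res <- list(method = "t_student", statistic = unname(tt$statistic),
                  p_value = tt$p.value, significant = tt$p.value < alpha,
                  no_difference = FALSE, normality = sw)
    } else {
      wt <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))
      res <- list(method = "wilcoxon", statistic = unname(wt$statistic),
                  p_value = wt$p.value, significant = wt$p.value < alpha,
                  no_difference = FALSE, normality = sw)
    }
  }
  res$n <- n
  res$alpha <- alpha
  res$mean_reference <- mean(pv$reference)
  res$sd_reference <- sd(pv$reference)
  res$mean_test <- mean(pv$test)
  res$sd_test <- sd(pv$test)
  structure(res, class = "gait_paired_test")
}

#' @export
print.gait_paired_test <- function(x, ...) {
  cat(sprintf("Paired two-tailed comparison (n = %d)\n", x$n))
  cat(sprintf("  reference %.3f +/- %.3f vs test %.3f +/- %.3f\n",
              x$mean_reference, x$sd_reference, x$mean_test, x$sd_test))
  if (isTRUE(x$no_difference)) {
    cat("  identical systems: no-difference convention (p = 1)\n")
  } else {
    cat(sprintf("  gate: Shapiro-Wilk p = %.4g -> %s\n",
                x$normality$p_value,
                if (x$method == "t_student") "paired t-test" else "Wilcoxon signed-rank"))
  }
  cat(sprintf("  statistic = %.4g, p = %.4g (%ssignificant at alpha = %g)\n",
              x$statistic, x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @rdname paired_compare
#' @param x A `gait_paired_test` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gait_paired_test <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, p_value = x$p_value,
         significant = x$significant, n = x$n,
         shapiro_W = x$normality$W, shapiro_p = x$normality$p_value,
         no_difference = isTRUE(x$no_difference))
}

#' @rdname paired_compare
#' @exportS3Method generics::glance
glance.gait_paired_test <- function(x, ...) {
  tibble(n = x$n, method = x$method, p_value = x$p_value,
         significant = x$significant, alpha = x$alpha)
}
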