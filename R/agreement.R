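#' Classify systematic errors and the level of agreement
#'
#' Deterministic rule engine mapping the Passing-Bablok confidence
#' intervals and the Bland-Altman bias interval to error flags and an
#' agreement level:
#'
#' * proportional systematic error: the slope interval excludes 1;
#' * constant systematic error: the intercept interval excludes 0 OR the
#'   bias interval excludes 0 (either detector suffices);
#' * level: `agreement` when neither error fires, `very_close_agreement`
#'   when only a constant error fires (removable by zeroing the bias), and
#'   `no_agreement` whenever a proportional error fires.
#'
#' Interval endpoints exactly at 1 (slope) or 0 (intercept, bias) count as
#' containing the value, so boundary cases never fire a flag; interval
#' width alone never fires a flag either.
#'
#' @param slope_ci Length-2 numeric: Passing-Bablok slope interval.
#' @param intercept_ci Length-2 numeric: Passing-Bablok intercept interval.
#' @param bias_ci Length-2 numeric: Bland-Altman bias interval.
#' @param parameter Optional parameter name carried into the verdict.
#' @param context Optional named list (e.g. the paired-test p-value) carried
#'   into the rationale for reporting; it never affects the verdict.
#' @return An object of class `agreement_verdict` with the two error flags,
#'   the `level` and a `rationale` character vector of fired rules.
#' @examples
#' classify_agreement(slope_ci = c(1.64, 2.69),
#'                    intercept_ci = c(-0.28, 0.13),
#'                    bias_ci = c(-0.42, -0.32))
#' @export
classify_agreement <- function(slope_ci, intercept_ci, bias_ci,
                               parameter = NA_character_, context = list()) {
  check_interval <- function(ci, what) {
    ci <- as.numeric(ci)
    if (length(ci) != 2L || any(!is.finite(ci))) {
      abort(sprintf("%s interval must be two finite numbers.", what),
            class = "gaitagree_error_input")
    }
    if (ci[1] > ci[2]) {
      abort(sprintf("%s interval is inverted (lower > upper).", what),
            class = "gaitagree_error_input")
    }
    ci
  }
  slope_ci <- check_interval(slope_ci, "Slope")
  intercept_ci <- check_interval(intercept_ci, "Intercept")
  bias_ci <- check_interval(bias_ci, "Bias")

  excludes <- function(ci, value) value < ci[1] || value > ci[2]
  proportional <- excludes(slope_ci, 1)
  const_intercept <- excludes(intercept_ci, 0)
  const_bias <- excludes(bias_ci, 0)
  constant <- const_intercept || const_bias

  rationale <- character()
  if (proportional) {
    rationale <- c(rationale, sprintf(
      "proportional: slope CI [%.4g, %.4g] excludes 1", slope_ci[1], slope_ci[2]))
  }
  if (const_intercept) {
    rationale <- c(rationale, sprintf(
      "constant: intercept CI [%.4g, %.4g] excludes 0",
      intercept_ci[1], intercept_ci[2]))
  }
  if (const_bias) {
    rationale <- c(rationale, sprintf(
      "constant: bias CI [%.4g, %.4g] excludes 0", bias_ci[1], bias_ci[2]))
  }
  if (!length(rationale)) rationale <- "all intervals contain their identity values"

  level <- if (proportional) {
    "no_agreement"
  } else if (constant) {
    "very_close_agreement"
  } else {
    "agreement"
  }

  structure(
    list(parameter = parameter, proportional_error = proportional,
         constant_error = constant, level = level, rationale = rationale,
         context = context),
    class = "agreement_verdict")
}

#' @export
print.agreement_verdict <- function(x, ...) {
  lab <- c(agreement = "Agreement",
           very_close_agreement = "Very close agreement",
           no_agreement = "No agreement")[[x$level]]
  hdr <- if (is.na(x$parameter)) lab else sprintf("%s: %s", x$parameter, lab)
  cat(hdr, "\n")
  for (r in x$rationale) cat("  -", r, "\n")
  invisible(x)
}

#' @rdname classify_agreement
#' @param x An `agreement_verdict` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.agreement_verdict <- function(x, ...) {
  tibble(parameter = x$parameter, level = x$level,
         proportional_error = x$proportional_error,
         constant_error = x$constant_error,
         rationale = paste(x$rationale, collapse = "; "))
}

#' Classify a table of precomputed intervals
#'
#' Row-wise application of [classify_agreement()] to a tibble of intervals,
#' the classification-only entry point for studies where the per-subject
#' data are unavailable but the fitted intervals are published. Expects the
#' column layout of [psp_gait_intervals()]: `lb_m`, `ub_m`, `lb_q`, `ub_q`,
#' `lb_b`, `ub_b` and optionally `parameter`.
#'
#' @param intervals A data frame of interval bounds, one row per parameter.
#' @return A tibble with `parameter`, `level`, `proportional_error`,
#'   `constant_error` and `rationale`.
#' @examples
#' classify_intervals(psp_gait_intervals())
#' @export
classify_intervals <- function(intervals) {
  need <- c("lb_m", "ub_m", "lb_q", "ub_q", "lb_b", "ub_b")
  if (!all(need %in% names(intervals))) {
    abort(sprintf("`intervals` must contain columns: %s",
                  paste(need, collapse = ", ")),
          class = "gaitagree_error_input")
  }
  intervals <- as_tibble(intervals)
  if (!"parameter" %in% names(intervals)) {
    intervals$parameter <- sprintf("row_%d", seq_len(nrow(intervals)))
  }
  purrr::pmap(
    select(intervals, "parameter", dplyr::all_of(need)),
    function(parameter, lb_m, ub_m, lb_q, ub_q, lb_b, ub_b) {
      tidy(classify_agreement(c(lb_m, ub_m), c(lb_q, ub_q), c(lb_b, ub_b),
                              parameter = parameter))
    }) |>
    bind_rows()
}
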