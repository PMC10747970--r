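#' Run the full two-system agreement pipeline
#'
#' Orchestrates, per parameter: trial/side averaging, the normality-gated
#' paired comparison, Passing-Bablok regression, Bland-Altman analysis and
#' the agreement classification. A parameter failing a stage (for example
#' too few complete pairs, or a degenerate Passing-Bablok fit) is reported
#' with its failure message; the other parameters proceed. The run is
#' deterministic given the input records and options.
#'
#' @param records Raw records tibble ([read_paired_csv()] /
#'   [generate_gait()] output), or an already-averaged paired tibble with
#'   `parameter`, `subject_id`, `reference`, `test` columns.
#' @param alpha Significance level for all stages (default 0.05).
#' @param loa_multiplier Limits-of-agreement half-width in SD units
#'   (default 1.96).
#' @return An object of class `gait_agreement`: a list with per-parameter
#'   results (`summary`, `test`, `pb`, `ba`, `verdict`, or `error`), the
#'   options used and the package version.
#' @examples
#' cfg <- synthetic_config(seed = 11)
#' report <- gait_agreement(generate_gait(cfg))
#' tidy(report)
#' @export
gait_agreement <- function(records, alpha = 0.05, loa_multiplier = 1.96) {
  check_alpha(alpha)
  paired <- if (all(c("reference", "test") %in% names(records))) {
    as_tibble(records)
  } else {
    average_trials(records)
  }
  if (!"parameter" %in% names(paired)) paired$parameter <- "value"
  params <- unique(paired$parameter)
  if (!length(params)) {
    abort("No analyzable parameter in the input.",
          class = "gaitagree_error_empty")
  }

  results <- purrr::map(params, function(p) {
    slice <- filter(paired, .data$parameter == p)
    tryCatch({
      pv <- paired_values(slice, min_n = 3L)
      summary_tbl <- tibble(
        system = c("reference", "test"),
        mean = c(mean(pv$reference), mean(pv$test)),
        sd = c(sd(pv$reference), sd(pv$test)),
        n = pv$n)
      test <- paired_compare(slice, alpha = alpha)
      pb <- pb_fit(slice, alpha = alpha)
      ba <- ba_fit(slice, alpha = alpha, loa_multiplier = loa_multiplier)
      verdict <- classify_agreement(
        slope_ci = pb$m_ci, intercept_ci = pb$q_ci, bias_ci = ba$bias_ci,
        parameter = p,
        context = list(paired_p = test$p_value, paired_method = test$method))
      list(parameter = p, summary = summary_tbl, test = test, pb = pb,
           ba = ba, verdict = verdict, error = NULL)
    }, error = function(e) {
      inform(sprintf("Parameter '%s' failed: %s", p, conditionMessage(e)))
      list(parameter = p, summary = NULL, test = NULL, pb = NULL, ba = NULL,
           verdict = NULL, error = conditionMessage(e))
    })
  })
  names(results) <- params
  ok <- purrr::map_lgl(results, ~ is.null(.x$error))
  if (!any(ok)) {
    abort("Every parameter failed; nothing to report.",
          class = "gaitagree_error_empty")
  }
  structure(
    list(parameters = results,
         options = list(alpha = alpha, loa_multiplier = loa_multiplier,
                        difference_convention = "reference_minus_test"),
         version = as.character(utils::packageVersion("gaitagree"))),
    class = "gait_agreement")
}

#' @export
print.gait_agreement <- function(x, ...) {
  cat(sprintf("Two-system gait agreement report (%d parameter(s), alpha = %g)\n\n",
              length(x$parameters), x$options$alpha))
  print(tidy(x))
  invisible(x)
}

#' @rdname gait_agreement
#' @param x A `gait_agreement` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gait_agreement <- function(x, ...) {
  purrr::map(x$parameters, function(res) {
    if (!is.null(res$error)) {
      return(tibble(parameter = res$parameter, level = NA_character_,
                    error = res$error))
    }
    tibble(
      parameter = res$parameter,
      n = res$ba$n,
      mean_reference = res$summary$mean[1], sd_reference = res$summary$sd[1],
      mean_test = res$summary$mean[2], sd_test = res$summary$sd[2],
      p_value = res$test$p_value, test_type = res$test$method,
      m = res$pb$m, lb_m = res$pb$m_ci[1], ub_m = res$pb$m_ci[2],
      q = res$pb$q, lb_q = res$pb$q_ci[1], ub_q = res$pb$q_ci[2],
      bias = res$ba$bias, lb_b = res$ba$bias_ci[1], ub_b = res$ba$bias_ci[2],
      lb_loa = res$ba$loa[1], ub_loa = res$ba$loa[2],
      proportional_error = res$verdict$proportional_error,
      constant_error = res$verdict$constant_error,
      level = res$verdict$level,
      error = NA_character_)
  }) |> bind_rows()
}

#' @rdname gait_agreement
#' @exportS3Method generics::glance
glance.gait_agreement <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_parameters = nrow(td),
    n_failed = sum(!is.na(td$error)),
    n_agreement = sum(td$level == "agreement", na.rm = TRUE),
    n_very_close = sum(td$level == "very_close_agreement", na.rm = TRUE),
    n_no_agreement = sum(td$level == "no_agreement", na.rm = TRUE),
    alpha = x$options$alpha)
}

# study-style tables, rounded to 2 decimals half away from zero
report_tables <- function(report) {
  td <- filter(tidy(report), is.na(.data$error))
  r2 <- function(v) round_half_away(v, 2)
  list(
    summary = tibble(parameter = td$parameter,
                     mean_reference = r2(td$mean_reference),
                     sd_reference = r2(td$sd_reference),
                     mean_test = r2(td$mean_test), sd_test = r2(td$sd_test),
                     p_value = signif(td$p_value, 3), test_type = td$test_type),
    passing_bablok = tibble(parameter = td$parameter, m = r2(td$m),
                            lb_m = r2(td$lb_m), ub_m = r2(td$ub_m),
                            q = r2(td$q), lb_q = r2(td$lb_q), ub_q = r2(td$ub_q)),
    bland_altman = tibble(parameter = td$parameter, bias = r2(td$bias),
                          lb_b = r2(td$lb_b), ub_b = r2(td$ub_b),
                          lb_loa = r2(td$lb_loa), ub_loa = r2(td$ub_loa)),
    agreement = tibble(parameter = td$parameter, level = td$level,
                       error_types = purrr::map2_chr(
                         td$constant_error, td$proportional_error,
                         function(ce, pe) {
                           if (ce && pe) "constant and proportional systematic errors"
                           else if (pe) "proportional systematic error"
                           else if (ce) "constant systematic error"
                           else "/"
                         }))
  )
}

#' Write a full agreement report to disk
#'
#' Serializes a [gait_agreement()] report as a lossless JSON document plus
#' four CSV tables (per-system summaries with paired-test results,
#' Passing-Bablok intervals, Bland-Altman intervals, agreement verdicts).
#' JSON keeps full double precision; the CSV tables are rounded to two
#' decimals (half away from zero).
#'
#' @param report A `gait_agreement` object.
#' @param path Output path for the JSON document.
#' @param tables_dir Optional directory for the CSV tables; created if
#'   missing. `NULL` (default) skips the CSVs.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path, tables_dir = NULL) {
  stopifnot(inherits(report, "gait_agreement"))
  td <- tidy(report)
  if (all(!is.na(td$error))) {
    abort("Report contains no successful parameter; nothing written.",
          class = "gaitagree_error_empty")
  }
  payload <- list(
    tool = "gaitagree", version = report$version,
    options = report$options,
    parameters = td
  )
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  if (!is.null(tables_dir)) {
    dir.create(tables_dir, recursive = TRUE, showWarnings = FALSE)
    tabs <- report_tables(report)
    readr::write_csv(tabs$summary, file.path(tables_dir, "system_summary.csv"))
    readr::write_csv(tabs$passing_bablok, file.path(tables_dir, "passing_bablok.csv"))
    readr::write_csv(tabs$bland_altman, file.path(tables_dir, "bland_altman.csv"))
    readr::write_csv(tabs$agreement, file.path(tables_dir, "agreement.csv"))
  }
  invisible(path)
}

#' Read back a JSON agreement report
#'
#' @param path Path to a JSON document written by [write_report()].
#' @return A list with `options` and a `parameters` tibble.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gaitagree_error_io")
  }
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$parameters <- as_tibble(doc$parameters)
  doc
}
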