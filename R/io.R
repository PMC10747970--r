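#' Read tidy paired gait records from CSV
#'
#' Reads a long-format CSV of per-trial gait measurements from two systems
#' into a validated tibble of raw records. The canonical columns are
#' `subject_id`, `parameter`, `trial`, `side`, `system`, `value`; files using
#' other column names are accepted through `schema`, a named character vector
#' mapping canonical names to the file's names (e.g.
#' `c(subject_id = "id", value = "measurement")`). `trial` and `side` are
#' optional in the file and default to 1 and `"na"`.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names.
#' @return A tibble with columns `subject_id`, `parameter`, `trial`, `side`,
#'   `system`, `value`, one row per input row, in file order.
#' @examples
#' path <- system.file("extdata", "synthetic_gait_demo.csv", package = "gaitagree")
#' records <- read_paired_csv(path)
#' dplyr::count(records, parameter, system)
#' @export
read_paired_csv <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "gaitagree_error_io")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  canonical <- c("subject_id", "parameter", "trial", "side", "system", "value")
  mapping <- stats::setNames(canonical, canonical)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), canonical)
    if (length(bad)) {
      abort(sprintf("Unknown schema entries: %s", paste(bad, collapse = ", ")),
            class = "gaitagree_error_schema")
    }
    mapping[names(schema)] <- schema
  }
  required <- c("subject_id", "parameter", "system", "value")
  missing_cols <- required[!mapping[required] %in% names(raw)]
  if (length(missing_cols)) {
    abort(sprintf("Missing required column(s): %s",
                  paste(mapping[missing_cols], collapse = ", ")),
          class = "gaitagree_error_schema")
  }
  out <- tibble(
    subject_id = raw[[mapping[["subject_id"]]]],
    parameter = raw[[mapping[["parameter"]]]],
    trial = if (mapping[["trial"]] %in% names(raw)) raw[[mapping[["trial"]]]] else "1",
    side = if (mapping[["side"]] %in% names(raw)) raw[[mapping[["side"]]]] else "na",
    system = raw[[mapping[["system"]]]],
    value = raw[[mapping[["value"]]]]
  )
  if (nrow(out) == 0L) return(mutate(out, trial = integer(), value = double()))

  value_num <- suppressWarnings(as.numeric(out$value))
  bad_rows <- which(!is.na(out$value) & is.na(value_num))
  if (length(bad_rows)) {
    abort(sprintf("Non-numeric value(s) in column '%s' at data row(s): %s",
                  mapping[["value"]], paste(bad_rows, collapse = ", ")),
          class = "gaitagree_error_parse")
  }
  trial_num <- suppressWarnings(as.integer(out$trial))
  bad_trial <- which(!is.na(out$trial) & is.na(trial_num))
  if (length(bad_trial)) {
    abort(sprintf("Non-integer trial index at data row(s): %s",
                  paste(bad_trial, collapse = ", ")),
          class = "gaitagree_error_parse")
  }
  bad_system <- which(!out$system %in% c("reference", "test"))
  if (length(bad_system)) {
    abort(sprintf("Unknown system label(s) %s at data row(s): %s (expected 'reference' or 'test')",
                  paste(unique(out$system[bad_system]), collapse = ", "),
                  paste(bad_system, collapse = ", ")),
          class = "gaitagree_error_value")
  }
  bad_side <- which(!out$side %in% c("left", "right", "na"))
  if (length(bad_side)) {
    abort(sprintf("Unknown side label(s) at data row(s): %s (expected 'left', 'right' or 'na')",
                  paste(bad_side, collapse = ", ")),
          class = "gaitagree_error_value")
  }
  if (any(!is.finite(value_num))) {
    abort("All values must be finite.", class = "gaitagree_error_value")
  }
  mutate(out, trial = trial_num, value = value_num)
}

#' Average trials and sides into per-subject paired values
#'
#' Collapses raw per-trial records to one value per (subject, parameter,
#' system) by taking the arithmetic mean over all trials and sides, then
#' pairs the two systems. Subjects observed under only one system for a
#' parameter are dropped from that parameter with a warning (listwise
#' deletion; missing values are never imputed). Unequal trial counts between
#' systems are accepted.
#'
#' @param records A tibble of raw records as returned by [read_paired_csv()]
#'   or [generate_gait()].
#' @return A tibble with columns `parameter`, `subject_id`, `reference`,
#'   `test`: one row per complete subject-parameter pair.
#' @examples
#' cfg <- synthetic_config(n_subjects = 5, seed = 1)
#' average_trials(generate_gait(cfg))
#' @export
average_trials <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("subject_id", "parameter", "system", "value") %in% names(records))) {
    abort("`records` must have subject_id, parameter, system and value columns.",
          class = "gaitagree_error_input")
  }
  averaged <- records |>
    group_by(.data$parameter, .data$subject_id, .data$system) |>
    summarise(value = mean(.data$value), .groups = "drop")
  wide <- tidyr::pivot_wider(averaged, names_from = "system",
                             values_from = "value")
  for (col in c("reference", "test")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  dropped <- filter(wide, is.na(.data$reference) | is.na(.data$test))
  if (nrow(dropped) > 0L) {
    warn(sprintf(
      "Dropped %d subject-parameter pair(s) observed under only one system: %s",
      nrow(dropped),
      paste(sprintf("%s/%s", dropped$subject_id, dropped$parameter), collapse = ", ")))
  }
  wide |>
    filter(!is.na(.data$reference) & !is.na(.data$test)) |>
    select("parameter", "subject_id", "reference", "test") |>
    arrange(.data$parameter, .data$subject_id)
}

#' Published summary values from a PSP wearable-validation gait study
#'
#' Per-parameter mean and standard deviation of six spatiotemporal gait
#' parameters measured in 15 people with progressive supranuclear palsy by
#' an optoelectronic reference system and a wearable inertial test system,
#' as published in a validation study of the wearable system. These moments
#' are the defaults of [synthetic_config()] (reference column) and the
#' anchor for the bias identity `bias = mean(reference) - mean(test)`.
#'
#' @return A tibble with columns `parameter`, `units`, `system`, `mean`,
#'   `sd`, `p_value`, `test_type` (the published paired-test results).
#' @seealso [psp_gait_intervals()]
#' @export
psp_gait_moments <- function() {
  pars <- .gait_parameters()
  ref <- tibble(
    parameter = pars$parameter, units = pars$units, system = "reference",
    mean = c(91.72, 1.36, 0.61, 63.96, 36.83, 0.41),
    sd = c(14.23, 0.33, 0.20, 2.92, 3.92, 0.10)
  )
  tst <- tibble(
    parameter = pars$parameter, units = pars$units, system = "test",
    mean = c(99.14, 1.21, 0.65, 62.12, 36.88, 0.78),
    sd = c(14.28, 0.30, 0.19, 2.11, 2.11, 0.20)
  )
  pv <- tibble(
    parameter = pars$parameter,
    p_value = c(0.002, 0.003, 0.192, 0.037, 0.159, 0.001),
    test_type = c("wilcoxon", "wilcoxon", "wilcoxon",
                  "wilcoxon", "wilcoxon", "t_student")
  )
  left_join(bind_rows(ref, tst), pv, by = "parameter")
}

#' Published agreement intervals from a PSP wearable-validation gait study
#'
#' Passing-Bablok slope/intercept estimates with 95% confidence intervals
#' and Bland-Altman bias with its 95% confidence interval and limits of
#' agreement, per spatiotemporal gait parameter, as published in the same
#' validation study as [psp_gait_moments()]. Feeding these intervals to
#' [classify_intervals()] reproduces the study's published agreement
#' verdicts.
#'
#' @return A tibble with one row per parameter and columns `m`, `lb_m`,
#'   `ub_m`, `q`, `lb_q`, `ub_q` (Passing-Bablok), `bias`, `lb_b`, `ub_b`,
#'   `lb_loa`, `ub_loa` (Bland-Altman), and the published `level` and error
#'   flags for reference.
#' @export
psp_gait_intervals <- function() {
  tibble(
    parameter = .gait_parameters()$parameter,
    units = .gait_parameters()$units,
    m = c(1.09, 1.03, 1.02, 0.63, 0.58, 2.10),
    lb_m = c(0.74, 0.63, 0.71, 0.46, 0.32, 1.64),
    ub_m = c(1.81, 1.74, 1.45, 0.85, 0.74, 2.69),
    q = c(-3.02, -0.10, 0.05, 23.09, 15.96, -0.06),
    lb_q = c(-67.89, -1.04, -0.17, 8.78, 10.13, -0.28),
    ub_q = c(30.17, 0.40, 0.22, 33.34, 25.68, 0.13),
    bias = c(-7.43, 0.15, -0.03, 0.84, -0.05, -0.37),
    lb_b = c(-11.36, 0.05, -0.08, 0.11, -1.37, -0.42),
    ub_b = c(-3.50, 0.25, 0.02, 1.57, 1.27, -0.32),
    lb_loa = c(-28.95, -0.40, -0.31, -3.17, -7.30, -0.63),
    ub_loa = c(14.10, 0.70, 0.25, 4.84, 7.20, -0.11),
    level = c("very_close_agreement", "very_close_agreement", "agreement",
              "no_agreement", "no_agreement", "no_agreement"),
    constant_error = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    proportional_error = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
}
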