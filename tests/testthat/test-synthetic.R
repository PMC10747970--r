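test_that("fixed seeds give bit-identical datasets", {
  cfg <- synthetic_config(seed = 42)
  expect_identical(generate_gait(cfg), generate_gait(cfg))
  expect_identical(generate_null_gait(cfg), generate_null_gait(cfg))
})

test_that("noiseless generation obeys the error model exactly", {
  # m = 1, q = 0, no noise, single trial: the two systems coincide
  cfg0 <- synthetic_config(n_subjects = 8, n_trials = 1,
                           sigma_ref = 0, sigma_test = 0, seed = 5)
  paired0 <- average_trials(generate_gait(cfg0))
  expect_equal(paired0$reference, paired0$test, tolerance = 0)

  # pure constant offset q = 5
  cfg5 <- synthetic_config(n_subjects = 8, n_trials = 1, q = 5,
                           sigma_ref = 0, sigma_test = 0, seed = 5)
  paired5 <- average_trials(generate_gait(cfg5)) |>
    dplyr::filter(parameter == "cadence")
  expect_equal(paired5$test - paired5$reference, rep(5, 8), tolerance = 1e-12)
})

test_that("noiseless proportional+constant error is recovered exactly by PB", {
  cfg <- synthetic_config(
    n_subjects = 15, n_trials = 1, sigma_ref = 0, sigma_test = 0,
    parameters = tibble::tibble(parameter = "stride_length",
                                truth_mean = 0.41, truth_sd = 0.10,
                                m = 2.10, q = -0.06),
    seed = 99)
  paired <- average_trials(generate_gait(cfg))
  fit <- pb_fit(paired)
  expect_equal(fit$m, 2.10, tolerance = 1e-12)
  expect_equal(fit$q, -0.06, tolerance = 1e-12)
})

test_that("consistent kinematics hold exactly on the truth layer", {
  cfg <- synthetic_config(n_subjects = 10, n_trials = 1,
                          sigma_ref = 0, sigma_test = 0,
                          consistent_kinematics = TRUE, seed = 3)
  wide <- average_trials(generate_gait(cfg)) |>
    dplyr::select(parameter, subject_id, reference) |>
    tidyr::pivot_wider(names_from = parameter, values_from = reference)
  expect_equal(wide$stance_phase + wide$swing_phase, rep(100, 10))
  expect_equal(wide$cycle_duration, 120 / wide$cadence)
  expect_equal(wide$speed, wide$stride_length / wide$cycle_duration)
})

test_that("sample moments of reference values match the configured moments", {
  cfg <- synthetic_config(
    n_subjects = 4000, n_trials = 1,
    parameters = tibble::tibble(parameter = "speed", truth_mean = 0.61,
                                truth_sd = 0.20, sigma_ref = 0.0122,
                                sigma_test = 0.0122),
    seed = 1234)
  ref <- generate_gait(cfg) |> dplyr::filter(system == "reference")
  expect_equal(mean(ref$value), 0.61, tolerance = 0.02)
  expect_equal(sd(ref$value), sqrt(0.20^2 + 0.0122^2), tolerance = 0.02)
})

test_that("null generation is symmetric: mean difference near zero", {
  cfg <- synthetic_config(
    n_subjects = 2000, n_trials = 1,
    parameters = tibble::tibble(parameter = "speed", truth_mean = 0.61,
                                truth_sd = 0.20),
    seed = 77)
  paired <- average_trials(generate_null_gait(cfg))
  se <- sd(paired$reference - paired$test) / sqrt(nrow(paired))
  expect_lt(abs(mean(paired$reference - paired$test)), 4 * se)
})

test_that("increasing q shifts the Bland-Altman bias by -q in expectation", {
  base <- function(qval) {
    cfg <- synthetic_config(
      n_subjects = 500, n_trials = 1, q = qval,
      parameters = tibble::tibble(parameter = "cadence", truth_mean = 91.72,
                                  truth_sd = 14.23, m = 1, q = qval),
      seed = 11)
    ba_fit(average_trials(generate_gait(cfg)))$bias
  }
  # identical seed: the noise realisation cancels in the contrast
  expect_equal(base(5) - base(0), -5, tolerance = 1e-9)
})

test_that("phase percentages stay inside (0, 100) and truncation is bounded", {
  cfg <- synthetic_config(
    n_subjects = 200, n_trials = 2,
    parameters = tibble::tibble(parameter = "stance_phase", truth_mean = 95,
                                truth_sd = 10, sigma_ref = 8, sigma_test = 8,
                                lower = 0, upper = 100),
    seed = 4)
  vals <- generate_gait(cfg)$value
  expect_true(all(vals > 0 & vals < 100))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_subjects = 2), class = "gaitagree_error_config")
  expect_error(synthetic_config(sigma_ref = -1), class = "gaitagree_error_config")
  expect_error(
    synthetic_config(parameters = tibble::tibble(
      parameter = "stance_phase", truth_mean = 120, truth_sd = 1,
      lower = 0, upper = 100)),
    class = "gaitagree_error_config")
})
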