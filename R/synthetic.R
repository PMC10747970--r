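#' Configure the synthetic two-system gait generator
#'
#' Builds the generative configuration for paired gait datasets with a known
#' error structure. Each subject-parameter combination has a latent truth
#' drawn from a truncated Gaussian; the reference system observes
#' `truth + noise` and the test system observes `q + m * truth + noise`, so
#' `m` injects a proportional systematic error and `q` a constant one.
#'
#' Per-parameter defaults (`truth_mean`, `truth_sd`) are the reference-system
#' moments of [psp_gait_moments()]; measurement noise defaults to 2% of the
#' truth mean for both systems. Truncation bounds are the tighter of
#' truth_mean +/- 6 truth_sd and the physical range (positive values;
#' phase percentages in (0, 100)).
#'
#' @param n_subjects Number of subjects (default 15).
#' @param n_trials Trials per subject and system (default 4).
#' @param parameters Optional tibble overriding the per-parameter settings;
#'   must contain `parameter`, `truth_mean`, `truth_sd` and may contain `m`,
#'   `q`, `sigma_ref`, `sigma_test`, `lower`, `upper`.
#' @param m,q Proportional factor and constant offset applied to the test
#'   system, recycled across parameters (defaults 1 and 0: no systematic
#'   error).
#' @param sigma_ref,sigma_test Measurement noise SDs, recycled across
#'   parameters; `NULL` (default) means 2% of each truth mean.
#' @param heteroscedastic If `TRUE`, noise SD scales linearly with the
#'   latent truth (fan-shaped differences).
#' @param consistent_kinematics If `TRUE`, kinematic identities are enforced
#'   on the truth layer before noise: swing = 100 - stance,
#'   cycle = 120 / cadence (two steps per stride), speed = stride / cycle.
#' @param seed Integer seed; a fixed seed makes [generate_gait()] output
#'   bit-identical.
#' @return A list of class `synthetic_config`.
#' @examples
#' cfg <- synthetic_config(n_subjects = 15, seed = 42)
#' head(generate_gait(cfg))
#' @export
synthetic_config <- function(n_subjects = 15, n_trials = 4, parameters = NULL,
                             m = 1, q = 0, sigma_ref = NULL, sigma_test = NULL,
                             heteroscedastic = FALSE,
                             consistent_kinematics = FALSE, seed = NULL) {
  if (!is.numeric(n_subjects) || n_subjects < 3) {
    abort("`n_subjects` must be at least 3.", class = "gaitagree_error_config")
  }
  if (!is.numeric(n_trials) || n_trials < 1) {
    abort("`n_trials` must be a positive integer.", class = "gaitagree_error_config")
  }
  moments <- psp_gait_moments() |> filter(.data$system == "reference")
  base <- .gait_parameters() |>
    left_join(select(moments, "parameter", truth_mean = "mean", truth_sd = "sd"),
              by = "parameter")
  if (!is.null(parameters)) {
    need <- c("parameter", "truth_mean", "truth_sd")
    if (!all(need %in% names(parameters))) {
      abort("`parameters` must contain parameter, truth_mean and truth_sd.",
            class = "gaitagree_error_config")
    }
    base <- as_tibble(parameters)
    if (!"lower" %in% names(base)) base$lower <- 0
    if (!"upper" %in% names(base)) base$upper <- Inf
    if (!"units" %in% names(base)) base$units <- ""
  }
  np <- nrow(base)
  if (!"m" %in% names(base)) base$m <- rep_len(m, np)
  if (!"q" %in% names(base)) base$q <- rep_len(q, np)
  if (!"sigma_ref" %in% names(base)) {
    base$sigma_ref <- if (is.null(sigma_ref)) 0.02 * base$truth_mean else rep_len(sigma_ref, np)
  }
  if (!"sigma_test" %in% names(base)) {
    base$sigma_test <- if (is.null(sigma_test)) 0.02 * base$truth_mean else rep_len(sigma_test, np)
  }
  if (any(base$truth_sd < 0) || any(base$sigma_ref < 0) || any(base$sigma_test < 0)) {
    abort("Standard deviations must be non-negative.", class = "gaitagree_error_config")
  }
  if (any(base$truth_mean <= base$lower) || any(base$truth_mean >= base$upper)) {
    abort("Each truth_mean must lie inside the parameter's physical range.",
          class = "gaitagree_error_config")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
         parameters = base, heteroscedastic = isTRUE(heteroscedastic),
         consistent_kinematics = isTRUE(consistent_kinematics),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "synthetic_config"
  )
}

# truncated-normal draw by rejection: 6 SD or the physical range, whichever
# is tighter; hard failure after 100 rounds
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  lo <- max(lower, mean - 6 * sd)
  hi <- min(upper, mean + 6 * sd)
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > 100L) {
      abort("Truncated-normal sampling failed after 100 retries.",
            class = "gaitagree_error_generation")
    }
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Generate a synthetic paired two-system gait dataset
#'
#' Draws latent per-subject truths and per-trial observations under the
#' error model of [synthetic_config()]: `reference = truth + e_ref`,
#' `test = q + m * truth + e_test`, with Gaussian noise. Phase percentages
#' are clipped to (0, 100) after noise. With a fixed seed the output is
#' bit-identical across calls.
#'
#' @param config A [synthetic_config()] object.
#' @return A tibble of raw records (`subject_id`, `parameter`, `trial`,
#'   `side`, `system`, `value`) ready for [average_trials()].
#' @export
generate_gait <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  run <- function() .generate_impl(config)
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

.generate_impl <- function(config) {
  pars <- config$parameters
  ns <- config$n_subjects
  nt <- config$n_trials
  subjects <- sprintf("S%02d", seq_len(ns))

  truth <- pars |>
    mutate(draws = purrr::pmap(
      list(.data$truth_mean, .data$truth_sd, .data$lower, .data$upper),
      function(mu, s, lo, hi) rtrunc_norm(ns, mu, s, lo, hi))) |>
    select("parameter", "draws") |>
    tidyr::unnest_longer("draws", values_to = "truth") |>
    mutate(subject_id = rep(subjects, times = nrow(pars)))

  if (config$consistent_kinematics) {
    wide <- tidyr::pivot_wider(truth, names_from = "parameter", values_from = "truth")
    if (all(c("stance_phase", "swing_phase") %in% names(wide))) {
      wide$swing_phase <- 100 - wide$stance_phase
    }
    if (all(c("cadence", "cycle_duration") %in% names(wide))) {
      wide$cycle_duration <- 120 / wide$cadence
    }
    if (all(c("stride_length", "cycle_duration", "speed") %in% names(wide))) {
      wide$speed <- wide$stride_length / wide$cycle_duration
    }
    truth <- tidyr::pivot_longer(wide, -"subject_id", names_to = "parameter",
                                 values_to = "truth")
  }

  grid <- truth |>
    left_join(select(pars, "parameter", "truth_mean", "m", "q",
                     "sigma_ref", "sigma_test", "lower", "upper"),
              by = "parameter") |>
    tidyr::expand_grid(trial = seq_len(nt)) |>
    arrange(.data$parameter, .data$subject_id, .data$trial)

  scale_fac <- if (config$heteroscedastic) grid$truth / grid$truth_mean else 1
  n_obs <- nrow(grid)
  ref_val <- grid$truth + rnorm(n_obs, 0, grid$sigma_ref * scale_fac)
  test_val <- grid$q + grid$m * grid$truth + rnorm(n_obs, 0, grid$sigma_test * scale_fac)

  clip <- function(v, lo, hi) {
    eps <- 1e-9
    pmin(pmax(v, lo + eps * (is.finite(lo))), ifelse(is.finite(hi), hi - eps, v))
  }
  is_pct <- grid$parameter %in% c("stance_phase", "swing_phase")
  ref_val[is_pct] <- clip(ref_val[is_pct], 0, 100)
  test_val[is_pct] <- clip(test_val[is_pct], 0, 100)

  bind_rows(
    tibble(subject_id = grid$subject_id, parameter = grid$parameter,
           trial = grid$trial, side = "na", system = "reference",
           value = ref_val),
    tibble(subject_id = grid$subject_id, parameter = grid$parameter,
           trial = grid$trial, side = "na", system = "test",
           value = test_val)
  ) |>
    arrange(.data$parameter, .data$subject_id, .data$trial, .data$system)
}

#' Generate a null dataset (two noisy views of the same truth)
#'
#' As [generate_gait()] but with `m = 1` and `q = 0` forced for every
#' parameter: both systems observe the same latent truth with independent
#' Gaussian noise, so the expected between-system difference is zero. Used
#' for type-I-error calibration of the paired-test stage.
#'
#' @inheritParams generate_gait
#' @return A tibble of raw records.
#' @export
generate_null_gait <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  config$parameters$m <- 1
  config$parameters$q <- 0
  generate_gait(config)
}
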