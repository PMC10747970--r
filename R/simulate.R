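#' Type-I-error calibration of the gated paired-test stage
#'
#' Monte-Carlo check that the normality-gated paired comparison keeps its
#' nominal level: each replicate draws a null dataset ([generate_null_gait()]
#' with a single parameter; both systems observe the same Gaussian truth
#' with independent noise), runs [average_trials()] and [paired_compare()],
#' and records whether the null of no difference was rejected.
#'
#' @param n_reps Number of replicates (>= 100; default 5000).
#' @param n_subjects Subjects per replicate (default 15).
#' @param alpha Nominal significance level (default 0.05).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @param config Optional [synthetic_config()] to use as the null template;
#'   default is a single speed-like parameter with 2% noise and one trial.
#' @return A tibble with the rejection fraction, its Monte-Carlo standard
#'   error, `n_reps`, `n_subjects` and `alpha`.
#' @export
simulate_type1 <- function(n_reps = 5000, n_subjects = 15, alpha = 0.05,
                           seed = NULL, config = NULL) {
  if (n_reps < 100) {
    abort("`n_reps` must be at least 100.", class = "gaitagree_error_config")
  }
  if (is.null(config)) {
    config <- synthetic_config(
      n_subjects = n_subjects, n_trials = 1,
      parameters = tibble(parameter = "speed", truth_mean = 0.61,
                          truth_sd = 0.20, lower = 0, upper = Inf))
  }
  seeds <- derive_seeds(n_reps, seed)
  reject <- purrr::map_lgl(seeds, function(s) {
    config$seed <- s
    paired <- average_trials(generate_null_gait(config))
    paired_compare(paired, alpha = alpha)$significant
  })
  rate <- mean(reject)
  tibble(rejection_rate = rate,
         mc_se = sqrt(rate * (1 - rate) / n_reps),
         n_reps = n_reps, n_subjects = config$n_subjects, alpha = alpha)
}

#' Passing-Bablok slope recovery under a known proportional error
#'
#' Monte-Carlo parameter-recovery study: each replicate draws `n` latent
#' truths from `Normal(truth_mean, truth_sd^2)`, observes
#' `reference = truth + Normal(0, sigma^2)` and
#' `test = q + m * truth + Normal(0, sigma^2)`, fits Passing-Bablok
#' regression, and records the slope and intercept estimates. Defaults
#' reproduce a stride-length-like scenario with a strong proportional
#' error (`m = 2.10`, `q = -0.06`).
#'
#' @param n_reps Number of replicates (default 1000).
#' @param n Pairs per replicate (default 15).
#' @param truth_mean,truth_sd Latent truth moments (defaults 0.41, 0.10).
#' @param m,q Generative slope and intercept (defaults 2.10, -0.06).
#' @param sigma Measurement noise SD on both axes (default 0.02).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A tibble with the mean and SD of the recovered slopes and
#'   intercepts, the Monte-Carlo standard error of the mean slope, and the
#'   simulation settings.
#' @export
simulate_pb_recovery <- function(n_reps = 1000, n = 15, truth_mean = 0.41,
                                 truth_sd = 0.10, m = 2.10, q = -0.06,
                                 sigma = 0.02, seed = NULL) {
  if (n_reps < 100) {
    abort("`n_reps` must be at least 100.", class = "gaitagree_error_config")
  }
  seeds <- derive_seeds(n_reps, seed)
  fits <- purrr::map(seeds, function(s) {
    withr::with_seed(s, {
      truth <- rnorm(n, truth_mean, truth_sd)
      d <- tibble(reference = truth + rnorm(n, 0, sigma),
                  test = q + m * truth + rnorm(n, 0, sigma))
      fit <- pb_fit(d)
      c(fit$m, fit$q)
    })
  })
  slopes <- purrr::map_dbl(fits, 1)
  intercepts <- purrr::map_dbl(fits, 2)
  tibble(mean_slope = mean(slopes), sd_slope = sd(slopes),
         mean_intercept = mean(intercepts), sd_intercept = sd(intercepts),
         mc_se = sd(slopes) / sqrt(n_reps),
         n_reps = n_reps, n = n, m = m, q = q)
}

#' Coverage of the Passing-Bablok slope confidence interval
#'
#' Monte-Carlo coverage study: each replicate draws `n` latent truths from
#' `Normal(truth_mean, truth_sd^2)`, adds independent Gaussian noise of SD
#' `noise_sd` to both axes around the structural line
#' `test = intercept + slope * truth`, fits Passing-Bablok regression, and
#' records whether the slope confidence interval contains the generative
#' slope.
#'
#' @param n_reps Number of replicates (default 1000).
#' @param n Pairs per replicate (default 50).
#' @param truth_mean,truth_sd Latent truth moments (defaults 10, 2).
#' @param noise_sd Measurement noise SD on both axes (default 0.3).
#' @param slope,intercept Generative structural line (defaults 1, 0).
#' @param alpha Interval level 1 - alpha (default 0.05).
#' @param seed Master seed; per-replicate seeds are derived from it.
#' @return A tibble with `coverage_pct` (percent of replicates whose slope
#'   interval contains the generative slope), its Monte-Carlo standard
#'   error, and the simulation settings.
#' @export
simulate_pb_coverage <- function(n_reps = 1000, n = 50, truth_mean = 10,
                                 truth_sd = 2, noise_sd = 0.3, slope = 1,
                                 intercept = 0, alpha = 0.05, seed = NULL) {
  if (n_reps < 100) {
    abort("`n_reps` must be at least 100.", class = "gaitagree_error_config")
  }
  seeds <- derive_seeds(n_reps, seed)
  covered <- purrr::map_lgl(seeds, function(s) {
    withr::with_seed(s, {
      truth <- rnorm(n, truth_mean, truth_sd)
      d <- tibble(reference = truth + rnorm(n, 0, noise_sd),
                  test = intercept + slope * truth + rnorm(n, 0, noise_sd))
      ci <- pb_fit(d, alpha = alpha)$m_ci
      ci[1] <= slope && slope <= ci[2]
    })
  })
  pct <- 100 * mean(covered)
  tibble(coverage_pct = pct,
         mc_se_pct = 100 * sqrt(mean(covered) * (1 - mean(covered)) / n_reps),
         n_reps = n_reps, n = n, slope = slope, alpha = alpha)
}
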