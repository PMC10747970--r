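# Independent brute-force oracle for Passing-Bablok Procedure I.
# Deliberately dumb: explicit double loop, explicit shifted order statistics.
oracle_pb <- function(x, y, alpha = 0.05) {
  n <- length(x)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      s <- if (dx == 0) sign(dy) * Inf else dy / dx
      if (identical(s, -1)) next
      if (!is.infinite(s) && s == -1) next
      slopes <- c(slopes, s)
    }
  }
  slopes <- sort(slopes)
  N <- length(slopes)
  K <- sum(slopes < -1)
  m <- if (N %% 2 == 1) {
    slopes[(N + 1) / 2 + K]
  } else {
    (slopes[N / 2 + K] + slopes[N / 2 + 1 + K]) / 2
  }
  C <- qnorm(1 - alpha / 2) * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- (N - C) / 2
  M1 <- sign(M1) * floor(abs(M1) + 0.5)
  M2 <- N - M1 + 1
  lb <- slopes[M1 + K]
  ub <- slopes[M2 + K]
  q <- median(y - m * x)
  list(slopes = slopes, N = N, K = K, m = m, m_ci = c(lb, ub),
       q = q, q_ci = c(median(y - ub * x), median(y - lb * x)))
}

# random paired dataset on a line with Gaussian noise on both axes
random_paired <- function(n, slope = 1, intercept = 0, noise = 0.3,
                          mu = 10, sigma = 2) {
  truth <- rnorm(n, mu, sigma)
  data.frame(reference = truth + rnorm(n, 0, noise),
             test = intercept + slope * truth + rnorm(n, 0, noise))
}

# tiny raw-records tibble builder
make_records <- function(subject_id, parameter, system, value,
                         trial = 1L, side = "na") {
  tibble::tibble(subject_id = subject_id, parameter = parameter,
                 trial = trial, side = side, system = system, value = value)
}
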