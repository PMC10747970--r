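test_that("pairwise slopes on exact lines are constant", {
  s1 <- pb_slopes(data.frame(reference = c(1, 2, 3), test = c(1, 2, 3)))
  expect_equal(s1$slopes, c(1, 1, 1))
  expect_equal(s1$K, 0L)

  s2 <- pb_slopes(data.frame(reference = c(0, 1, 2), test = c(1, 3, 5)))
  expect_equal(s2$slopes, c(2, 2, 2))
  expect_equal(s2$K, 0L)
})

test_that("pairwise slopes match a brute-force double loop on random data", {
  withr::with_seed(101, {
    for (i in 1:20) {
      n <- sample(4:12, 1)
      df <- random_paired(n, slope = runif(1, 0.5, 2), noise = 0.5)
      got <- pb_slopes(df)
      want <- oracle_pb(df$reference, df$test)
      expect_equal(got$slopes, want$slopes, tolerance = 1e-12)
      expect_equal(got$K, want$K)
      expect_equal(got$N, want$N)
    }
  })
})

test_that("tied-reference pairs yield signed infinities at the extremes", {
  df <- data.frame(reference = c(1, 1, 2, 3), test = c(1, 2, 3, 4))
  s <- pb_slopes(df)
  expect_equal(s$slopes[s$N], Inf)
  expect_equal(sum(is.infinite(s$slopes)), 1L)
  # identical duplicated points contribute nothing
  df2 <- data.frame(reference = c(1, 1, 2, 3), test = c(1, 1, 3, 4))
  expect_equal(sum(is.infinite(pb_slopes(df2)$slopes)), 0L)
})

test_that("slopes exactly equal to -1 are excluded and K counts slopes below -1", {
  df <- data.frame(reference = c(0, 1, 2, 3), test = c(3, 2, 1, 0))  # y = 3 - x
  expect_error(pb_slopes(df), class = "gaitagree_error_degenerate")
  df2 <- data.frame(reference = c(0, 1, 2, 3), test = c(6, 4, 2, 0))  # y = 6 - 2x
  s <- pb_slopes(df2)
  expect_equal(s$K, s$N)
  expect_true(all(s$slopes == -2))
})

test_that("noiseless lines are recovered exactly, including the intercept", {
  df <- data.frame(reference = c(0.2, 0.35, 0.41, 0.5, 0.62),
                   test = 2.10 * c(0.2, 0.35, 0.41, 0.5, 0.62) - 0.06)
  fit <- pb_fit(df)
  expect_equal(fit$m, 2.10, tolerance = 1e-12)
  expect_equal(fit$q, -0.06, tolerance = 1e-12)
  expect_true(fit$linearity$linear)
  expect_equal(fit$linearity$H, 0)
})

test_that("full fit matches the brute-force oracle on seeded data, n <= 12", {
  withr::with_seed(202, {
    for (i in 1:20) {
      n <- sample(8:12, 1)
      df <- random_paired(n, slope = runif(1, 0.5, 2),
                          intercept = runif(1, -1, 1), noise = 0.4)
      fit <- pb_fit(df)
      want <- oracle_pb(df$reference, df$test)
      expect_equal(fit$m, want$m, tolerance = 1e-12)
      expect_equal(fit$m_ci, want$m_ci, tolerance = 1e-12)
      expect_equal(fit$q, want$q, tolerance = 1e-12)
      expect_equal(fit$q_ci, want$q_ci, tolerance = 1e-12)
    }
  })
})

test_that("swapping the axes inverts the slope", {
  withr::with_seed(303, {
    for (i in 1:20) {
      df <- random_paired(15, slope = runif(1, 0.5, 2), noise = 0.3)
      m_xy <- pb_fit(df)$m
      m_yx <- pb_fit(data.frame(reference = df$test, test = df$reference))$m
      expect_equal(m_yx, 1 / m_xy, tolerance = 1e-9)
    }
  })
})

test_that("the fit is equivariant under affine maps of the test axis", {
  withr::with_seed(404, df <- random_paired(15, noise = 0.3))
  fit <- pb_fit(df)
  a <- 2.5; b <- 1.7
  fit2 <- pb_fit(data.frame(reference = df$reference, test = a + b * df$test))
  expect_equal(fit2$m, b * fit$m, tolerance = 1e-9)
  expect_equal(fit2$q, a + b * fit$q, tolerance = 1e-9)
  expect_equal(fit2$m_ci, b * fit$m_ci, tolerance = 1e-9)
})

test_that("estimates always lie inside their own confidence intervals", {
  withr::with_seed(505, {
    for (i in 1:20) {
      df <- random_paired(sample(10:30, 1), slope = runif(1, 0.5, 2), noise = 0.5)
      fit <- pb_fit(df)
      expect_lte(fit$m_ci[1], fit$m)
      expect_gte(fit$m_ci[2], fit$m)
      expect_lte(fit$q_ci[1], fit$q)
      expect_gte(fit$q_ci[2], fit$q)
      expect_lte(fit$N, fit$n * (fit$n - 1) / 2)
    }
  })
})

test_that("samples too small for the requested level raise a CI-undefined error", {
  df <- data.frame(reference = c(1, 2, 3), test = c(1.1, 2.05, 3.2))
  err <- tryCatch(pb_fit(df), error = function(e) e)
  expect_s3_class(err, "gaitagree_error_ci_undefined")
  expect_true(is.numeric(err$estimates$m))  # point estimates carried along
})

test_that("cusum flags curvature but tolerates alternating residuals", {
  # convex data: residual signs run (+, then -, then +), so the cusum path
  # excursion grows like n/4 while the critical value grows like sqrt(n)
  x <- 1:40
  fitq <- pb_fit(data.frame(reference = x, test = x^2))
  expect_false(fitq$linearity$linear)

  # alternating-sign residuals around a known line: small cusum excursion
  n <- 20
  x2 <- seq(1, 10, length.out = n)
  y2 <- 2 * x2 + 0.1 * rep(c(1, -1), n / 2)
  lin <- cusum_linearity(data.frame(reference = x2, test = y2),
                         list(m = 2, q = 0))
  expect_equal(lin$H, 1 / sqrt(n))  # path oscillates between 1 and 0
  expect_true(lin$linear)
})

test_that("pb plot data exposes sorted points and both lines", {
  withr::with_seed(9, df <- random_paired(10))
  fit <- pb_fit(df)
  pd <- pb_plot_data(fit)
  expect_equal(pd$points$reference, sort(df$reference))
  expect_equal(pd$lines$slope, c(fit$m, 1))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
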