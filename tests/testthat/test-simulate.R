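test_that("closed-form ARFIMA autocovariances match known special cases", {
  # white noise
  g <- acvf_arfima(0, 5)
  expect_equal(g, c(1, rep(0, 5)))
  # lag-1 correlation d / (1 - d), persistent and anti-persistent
  g <- acvf_arfima(0.4, 1)
  expect_equal(g[2] / g[1], 0.4 / 0.6, tolerance = 1e-12)
  g <- acvf_arfima(-0.4, 4)
  expect_equal(g[2] / g[1], -0.4 / 1.4, tolerance = 1e-12)
  # anti-persistent: alternating sign would be wrong — correlations stay
  # negative beyond lag 0 with decreasing magnitude
  rho <- g[-1] / g[1]
  expect_true(all(rho < 0))
  expect_true(all(diff(abs(rho)) < 0))
  expect_error(acvf_arfima(0.5, 3), "d")
  expect_error(acvf_arfima(-0.6, 3), "d")
})

test_that("both exact samplers reproduce the target autocovariance", {
  # known-mean empirical covariances over many replicates, tiny n: this is
  # free of the sample-mean-removal bias that long-memory sample ACFs carry
  n <- 48
  reps <- 2500
  for (d in c(-0.3, 0.35)) {
    gam <- acvf_arfima(d, 4)
    set.seed(101)
    Xdl <- t(replicate(reps, stochent:::sample_durbin_levinson(
      acvf_arfima(d, n - 1), n)))
    Xce <- t(replicate(reps, stochent:::sample_circulant(
      function(l) acvf_arfima(d, l), n)))
    for (X in list(Xdl, Xce)) {
      emp <- emp_acvf0(X, 4)
      se <- sqrt(2 / (reps * n)) * gam[1] # rough SE of pooled covariances
      expect_true(all(abs(emp - gam) < 4 * se + 0.02))
    }
  }
})

test_that("simulated series are standardized, reproducible, and correctly labelled", {
  s <- simulate_fgn(0.3, 500, seed = 42)
  expect_s3_class(s, "sim_series")
  expect_lt(abs(mean(s$values)), 1e-12)
  expect_lt(abs(sd(s$values) - 1), 1e-12)
  expect_identical(s$values, simulate_fgn(0.3, 500, seed = 42)$values)
  expect_equal(s$true_alpha, 0.8)
  expect_equal(s$class_label, "stationary")

  b <- simulate_fgn(0.3, 500, seed = 42, integrate = TRUE)
  expect_equal(b$true_alpha, 1.8)
  expect_equal(b$class_label, "nonstationary")
  expect_lt(abs(mean(b$values)), 1e-12)
  # both backends standardized and deterministic at large n too
  big <- simulate_fgn(-0.2, 4096, seed = 7)
  expect_lt(abs(sd(big$values) - 1), 1e-12)
  expect_identical(big$values, simulate_fgn(-0.2, 4096, seed = 7)$values)
})

test_that("sample lag-1 ACF of fGn follows d/(1-d) at moderate memory", {
  # modest d keeps the O(n^{2d-1}) mean-removal bias within the allowance
  r1 <- mean(vapply(1:40, function(s) {
    stats::acf(simulate_fgn(0.2, 4096, seed = s)$values,
               plot = FALSE, lag.max = 1)$acf[2]
  }, numeric(1)))
  expect_lt(abs(r1 - 0.25), 3 * 0.02 / sqrt(40) + 0.015)
  # iid case: lag-1 ACF near zero
  r0 <- stats::acf(simulate_fgn(0, 1000, seed = 5)$values,
                   plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r0), 3 / sqrt(1000))
})

test_that("cumulative summation and differencing are inverse operations", {
  expect_equal(cumsum_series(c(1, 1, 1), standardize = FALSE), c(1, 2, 3))
  x <- rnorm(50)
  expect_equal(difference_series(cumsum_series(x, standardize = FALSE)),
               x[-1])
  expect_equal(difference_series(c(1, 2, 4)), c(1, 2))
  expect_equal(difference_series(rep(3, 5)), rep(0, 4))
})

test_that("d-to-alpha conversion reproduces the study grid and is monotone", {
  d_stat <- c(seq(-0.4, 0.4, by = 0.1), 0.49)
  expect_equal(alpha_from_d(d_stat),
               c(seq(0.1, 0.9, by = 0.1), 0.99))
  d_nonstat <- seq(-0.4, 0.4, by = 0.1)
  expect_equal(alpha_from_d(d_nonstat, was_differenced = TRUE),
               seq(1.1, 1.9, by = 0.1))
  expect_true(all(diff(alpha_from_d(seq(-0.49, 0.49, by = 0.01))) > 0))
})

test_that("series files round-trip through the readers and writers", {
  x <- rnorm(20)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".txt")
  write_series(x, p1)
  write_series(x, p2)
  expect_equal(read_series(p1), x, tolerance = 1e-12)
  expect_equal(read_series(p2), x, tolerance = 1e-12)
})
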