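test_that("contamination perturbs the documented number of positions, reproducibly", {
  x <- simulate_fgn(0, 250, seed = 31)$values
  ct <- contaminate(x, seed = 32)
  expect_length(ct$indices, 3) # ceiling(0.01 * 250)
  expect_equal(length(contaminate(rnorm(500), seed = 1)$indices), 5)
  expect_equal(length(contaminate(rnorm(1000), seed = 1)$indices), 10)
  # only flagged positions change, each at most once
  expect_equal(ct$values[-ct$indices], x[-ct$indices])
  expect_true(all(ct$values[ct$indices] != x[ct$indices]))
  # deterministic given seed; amplitude zero is the identity
  ct2 <- contaminate(x, seed = 32)
  expect_identical(ct$values, ct2$values)
  expect_equal(contaminate(x, amplitude_factor = 0, seed = 5)$values, x)
})

test_that("scaled-MAD detection flags gross spikes and almost never clean data", {
  x <- c(rep(0, 49), 100)
  x[1:49] <- rnorm(49, sd = 0.5)
  rep_ <- detect_outliers(x)
  expect_identical(rep_$flagged_indices, 50L)
  expect_lt(rep_$sd_ratio, 1)
  # nothing beyond 5 MADs: empty report, ratio 1
  r0 <- detect_outliers(rnorm(100, sd = 1e-3) + 10)
  expect_length(r0$flagged_indices, 0)
  expect_equal(r0$sd_ratio, 1)
  expect_warning(detect_outliers(rep(1, 20)), "MAD")
  # false positives on clean fGn are rare at the 5-MAD threshold
  n_flagged <- vapply(1:50, function(s) {
    length(detect_outliers(simulate_alpha(0.5, 500,
                                          child_seed(81, s))$values
    )$flagged_indices)
  }, integer(1))
  expect_lte(sum(n_flagged > 0), 3)
})

test_that("r adjustment follows the SD ratio and responds to outlier severity", {
  x <- rnorm(200)
  x[7] <- 40
  rep_ <- detect_outliers(x)
  expect_equal(adjusted_r(0.2, rep_), 0.2 * rep_$sd_ratio)
  # worked example: ratio 0.5 halves r
  fake <- rep_
  fake$sd_ratio <- 0.5
  expect_equal(adjusted_r(0.2, fake), 0.1)
  # empty report leaves r untouched
  expect_equal(adjusted_r(0.25, detect_outliers(rnorm(100))), 0.25,
               tolerance = 1e-12)
  # a more extreme outlier never increases the adjusted r
  r_adj <- vapply(c(10, 20, 40, 80), function(a) {
    y <- x
    y[7] <- a
    adjusted_r(0.25, detect_outliers(y))
  }, numeric(1))
  expect_true(all(diff(r_adj) <= 1e-12))
})

test_that("outlier removal drops exactly the flagged positions", {
  x <- rnorm(10)
  x[4] <- 50
  rep_ <- detect_outliers(x)
  expect_length(remove_outliers(x, rep_), 9)
  expect_equal(remove_outliers(x, rep_), x[-4])
  clean <- rnorm(50)
  expect_identical(remove_outliers(clean, detect_outliers(clean)), clean)
})

test_that("classification-guided cleaning recovers single spikes in fBm", {
  s <- simulate_alpha(1.5, 1000, seed = 91)
  x <- s$values
  p <- 500L
  x[p] <- x[p] + 10 * diff(range(s$values))
  # the spike flags increments p and p+1, which merge to position p
  dx_flags <- detect_outliers(difference_series(x))$flagged_indices
  expect_identical(dx_flags + 1L, c(p, p + 1L))
  out <- clean_with_classification(x)
  expect_equal(out$class_label, "nonstationary")
  expect_identical(out$removed_indices, p)
  expect_equal(out$cleaned_values, s$values[-p], tolerance = 1e-12)
})

test_that("stationary branch equals plain detect-and-remove; clean input untouched", {
  x <- simulate_alpha(0.5, 500, seed = 92)$values
  x[100] <- x[100] + 8 * diff(range(x))
  out <- clean_with_classification(x)
  expect_equal(out$class_label, "stationary")
  expect_equal(out$cleaned_values, remove_outliers(x, detect_outliers(x)))
  # clean fGn: nothing removed
  removed <- vapply(1:20, function(s) {
    clean_with_classification(simulate_alpha(0.7, 500,
                                             child_seed(93, s))$values
    )$removed_count
  }, integer(1))
  expect_lte(sum(removed), 2)
})

test_that("percent bias arithmetic", {
  expect_equal(percent_bias(1, 2), -50)
  expect_equal(percent_bias(2, 2), 0)
  expect_equal(percent_bias(1.476, 1.968), -25)
  expect_error(percent_bias(1, 0), "nonzero")
})
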