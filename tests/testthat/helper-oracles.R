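# Independent brute-force oracles used to validate the package's optimized
# implementations. These deliberately share no code with R/.

# SampEn match counts by direct double loop over template pairs.
sampen_counts_naive <- function(x, m, tol, tau = 1) {
  N <- length(x)
  nt <- N - m * tau
  A <- 0L
  B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i + (0:(m - 1)) * tau] - x[j + (0:(m - 1)) * tau]))
      if (dm <= tol) {
        B <- B + 1L
        if (abs(x[i + m * tau] - x[j + m * tau]) <= tol) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

# Whittle objective minimized by plain grid search.
fit_d_grid <- function(x, step = 1e-4) {
  pg <- periodogram(x)
  grid <- seq(-0.499, 0.499, by = step)
  q <- vapply(grid, whittle_objective, numeric(1), pg = pg)
  grid[which.min(q)]
}

# Empirical lag covariances assuming known mean zero (no mean removal),
# for validating the exact Gaussian samplers against the closed-form ACVF.
emp_acvf0 <- function(X, max_lag) {
  n <- ncol(X)
  vapply(0:max_lag, function(k) {
    mean(X[, seq_len(n - k)] * X[, seq_len(n - k) + k])
  }, numeric(1))
}
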