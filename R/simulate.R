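#' Autocovariance function of ARFIMA(0,d,0) fractional noise
#'
#' Closed-form autocovariances of the fractionally integrated white-noise
#' process with unit innovation variance:
#' \deqn{\gamma(0) = \Gamma(1-2d)/\Gamma(1-d)^2, \qquad
#'       \gamma(k) = \gamma(k-1)\,\frac{k-1+d}{k-d}.}
#' For `d = 0` this is white noise; for `d > 0` the process is persistent
#' (long-range dependent) and for `d < 0` anti-persistent.
#'
#' @param d fractional difference order, in the open interval (-0.5, 0.5).
#' @param max_lag largest lag to return (>= 0).
#' @return numeric vector of autocovariances at lags `0:max_lag`.
#' @export
#' @examples
#' acvf_arfima(0.4, 3)
#' # lag-1 autocorrelation is d / (1 - d)
#' g <- acvf_arfima(0.4, 1); g[2] / g[1]
acvf_arfima <- function(d, max_lag) {
  stopifnot(length(d) == 1, length(max_lag) == 1, max_lag >= 0)
  if (!is.finite(d) || abs(d) >= 0.5) {
    stop("'d' must lie in the open interval (-0.5, 0.5)")
  }
  # gamma(0) via lgamma for numerical stability as d -> 0.5
  g0 <- exp(lgamma(1 - 2 * d) - 2 * lgamma(1 - d))
  if (max_lag == 0) return(g0)
  k <- seq_len(max_lag)
  c(g0, g0 * cumprod((k - 1 + d) / (k - d)))
}

# Exact Gaussian sample with autocovariance gamma[1..n] (lags 0..n-1),
# Durbin-Levinson recursion. O(n^2); used for moderate n and as the
# fallback when circulant embedding is not nonnegative definite.
sample_durbin_levinson <- function(gamma, n) {
  z <- rnorm(n)
  x <- numeric(n)
  x[1] <- sqrt(gamma[1]) * z[1]
  if (n == 1) return(x)
  phi <- numeric(n - 1)
  v <- gamma[1]
  for (t in 1:(n - 1)) {
    if (t == 1) {
      phi_tt <- gamma[2] / gamma[1]
      phi[1] <- phi_tt
    } else {
      phi_tt <- (gamma[t + 1] - sum(phi[1:(t - 1)] * gamma[t:2])) / v
      phi[1:(t - 1)] <- phi[1:(t - 1)] - phi_tt * phi[(t - 1):1]
      phi[t] <- phi_tt
    }
    v <- v * (1 - phi_tt^2)
    m <- sum(phi[1:t] * x[t:1])
    x[t + 1] <- m + sqrt(v) * z[t + 1]
  }
  x
}

# Exact Gaussian sample via circulant embedding of the covariance.
# Returns NULL when the embedding (after a few size doublings) has
# negative eigenvalues beyond numerical noise.
sample_circulant <- function(acvf_fun, n) {
  m <- 2^ceiling(log2(2 * n))
  for (attempt in 1:5) {
    g <- acvf_fun(m / 2) # lags 0..m/2, length m/2 + 1
    circ <- c(g, g[(m / 2):2])
    ev <- Re(fft(circ))
    tol <- -1e-8 * max(ev)
    if (min(ev) >= tol) {
      ev <- pmax(ev, 0)
      z <- complex(real = rnorm(m), imaginary = rnorm(m))
      # Re(F [sqrt(ev) z]) / sqrt(m) has covariance equal to the embedded
      # circulant (z has complex variance 2, halved by taking Re)
      w <- fft(sqrt(ev) * z) / sqrt(m)
      return(Re(w)[1:n])
    }
    m <- m * 2
  }
  NULL
}

standardize <- function(x) (x - mean(x)) / sd(x)

#' Simulate fractional Gaussian noise / fractional Brownian motion
#'
#' Draws an exact Gaussian realization of an ARFIMA(0,d,0) process (a
#' fractional Gaussian noise, stationary) from its closed-form
#' autocovariance, optionally cumulatively summed to produce the
#' corresponding fractional Brownian motion (nonstationary). The returned
#' series is standardized to sample mean 0 and standard deviation 1.
#'
#' Sampling uses the Durbin-Levinson recursion for `n <= 2048` and circulant
#' embedding (with Durbin-Levinson fallback should the embedding fail to be
#' nonnegative definite) for longer series; both are exact for this family,
#' so no burn-in or truncation is involved.
#'
#' @param d fractional difference order in (-0.5, 0.5). The scaling exponent
#'   of the generated series is `alpha = d + 0.5` for fGn and `d + 1.5`
#'   after integration (fBm).
#' @param n series length, at least 16.
#' @param seed integer RNG seed; the same `(d, n, seed, integrate)` always
#'   yields the identical series.
#' @param integrate logical; cumulatively sum the noise to obtain fBm.
#' @return an object of class `"sim_series"`: a list with elements `values`
#'   (standardized series), `true_d`, `true_alpha`, `class_label`
#'   (`"stationary"` or `"nonstationary"`), `seed` and `integrate`.
#' @seealso [acvf_arfima()], [alpha_from_d()], [cumsum_series()]
#' @export
#' @examples
#' s <- simulate_fgn(0.3, 500, seed = 7)
#' s$true_alpha
#' round(mean(s$values), 12)
simulate_fgn <- function(d, n, seed, integrate = FALSE) {
  stopifnot(length(n) == 1, n >= 16)
  if (!is.finite(d) || abs(d) >= 0.5) {
    stop("'d' must lie in the open interval (-0.5, 0.5)")
  }
  n <- as.integer(n)
  x <- with_seed(seed, {
    if (n <= 2048) {
      sample_durbin_levinson(acvf_arfima(d, n - 1), n)
    } else {
      y <- sample_circulant(function(maxlag) acvf_arfima(d, maxlag), n)
      if (is.null(y)) sample_durbin_levinson(acvf_arfima(d, n - 1), n) else y
    }
  })
  if (integrate) x <- cumsum(x)
  structure(
    list(
      values = standardize(x),
      true_d = d,
      true_alpha = alpha_from_d(d, was_differenced = FALSE) + if (integrate) 1 else 0,
      class_label = if (integrate) "nonstationary" else "stationary",
      seed = as.integer(seed),
      integrate = integrate
    ),
    class = "sim_series"
  )
}

#' @export
print.sim_series <- function(x, ...) {
  cat(sprintf(
    "Simulated %s series: n = %d, d = %g, alpha = %g, seed = %d\n",
    x$class_label, length(x$values), x$true_d, x$true_alpha, x$seed
  ))
  invisible(x)
}

#' Cumulative summation (noise to motion)
#'
#' Cumulatively sums a series and, by default, standardizes the result to
#' mean 0 and SD 1 — the convention under which fBm datasets are analysed.
#'
#' @param x numeric series.
#' @param standardize standardize the summed series (default `TRUE`).
#' @return numeric series of the same length.
#' @export
cumsum_series <- function(x, standardize = TRUE) {
  y <- cumsum(x)
  if (standardize) standardize(y) else y
}

#' First difference of a series
#'
#' Returns `x[t] - x[t-1]`, length `n - 1`. Differencing converts a
#' nonstationary fBm (scaling exponent `alpha` in (1, 2)) into the stationary
#' fGn of its increments (`alpha - 1`).
#'
#' @param x numeric series of length >= 2.
#' @return numeric series of length `length(x) - 1`.
#' @export
difference_series <- function(x) {
  stopifnot(length(x) >= 2)
  diff(x)
}

#' Convert a fractional difference order to the scaling exponent
#'
#' The scaling exponent of the fGn/fBm model is linearly related to the
#' ARFIMA difference order: `alpha = (2 d + 1) / 2 = d + 0.5`. When the
#' estimate was obtained on differenced (increment) data, `d` is first
#' adjusted by adding 1, mapping onto the nonstationary range (1, 2).
#'
#' @param d difference order (estimate or true value).
#' @param was_differenced logical; was `d` estimated on differenced data?
#' @return scaling exponent `alpha`.
#' @export
#' @examples
#' alpha_from_d(0.49)              # 0.99, just below the 1/f boundary
#' alpha_from_d(0.4, TRUE)         # 1.9, strongly persistent fBm
alpha_from_d <- function(d, was_differenced = FALSE) {
  (2 * (d + ifelse(was_differenced, 1, 0)) + 1) / 2
}
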