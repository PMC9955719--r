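#' Sample Entropy SampEn(m, r, tau)
#'
#' Estimates the regularity of a series as the negative logarithm of the
#' conditional probability that template vectors of `m` observations
#' (elements `tau` samples apart) that match within tolerance `r` standard
#' deviations still match when extended to `m + 1` observations. Matching
#' uses the Chebyshev (maximum coordinate) distance, pairs are counted over
#' the whole record (not template-wise), and self-matches are excluded.
#' Both the length-`m` count `B` and the length-`(m+1)` count `A` run over
#' the same template index range `i = 1..N - m*tau`.
#'
#' The tolerance is anchored to the sample SD of the series *as provided*:
#' a contaminated series therefore uses its inflated SD, which is precisely
#' the outlier bias mechanism the cleaning tools in this package address.
#' Because `r` is in SD units, SampEn is invariant under affine
#' transformations of the data.
#'
#' @param x numeric series with `length(x) > (m + 1) * tau`.
#' @param m template length (>= 1; default 1).
#' @param r radius of similarity in multiples of the sample SD (default 0.25).
#' @param tau time delay between template elements (default 1).
#' @param sd_ref reference SD used to convert `r` into signal units; defaults
#'   to `sd(x)`. Pass 1 to interpret `r` as an absolute tolerance, or the SD
#'   of a cleaned series to apply an adjusted tolerance.
#' @return object of class `"sampen"`: list with match counts `A` and `B`,
#'   `value` (`-log(A/B)`, nats; `NA` when `A` or `B` is zero),
#'   `max_value` (the [max_sampen()] bound), `normalized`
#'   (`value / max_value`), `effective_tolerance` (signal units), and the
#'   parameters `m`, `r`, `tau`, `n`.
#' @references Richman & Moorman (2000) Am J Physiol Heart Circ Physiol 278:H2039.
#' @export
#' @examples
#' sampen(rnorm(500))
#' # absolute tolerance 0.5 on a small integer series
#' sampen(c(1, 5, 2, 8, 1, 5, 9), m = 1, r = 0.5, sd_ref = 1)
sampen <- function(x, m = 1, r = 0.25, tau = 1, sd_ref = NULL) {
  if (inherits(x, "sim_series")) x <- x$values
  stopifnot(m >= 1, r > 0, tau >= 1)
  n <- length(x)
  if (n <= (m + 1) * tau) stop("series too short for the requested (m, tau)")
  if (any(!is.finite(x))) stop("series contains non-finite values")
  if (is.null(sd_ref)) sd_ref <- sd(x)
  tol <- r * sd_ref
  cnt <- sampen_counts_cpp(as.numeric(x), as.integer(m), tol, as.integer(tau))
  A <- cnt[1]
  B <- cnt[2]
  value <- if (A > 0 && B > 0) -log(A / B) else NA_real_
  mx <- max_sampen(n, m, tau)
  structure(
    list(
      A = A, B = B, value = value, max_value = mx,
      normalized = if (is.na(value)) NA_real_ else value / mx,
      effective_tolerance = tol,
      m = m, r = r, tau = tau, n = n
    ),
    class = "sampen"
  )
}

#' @export
print.sampen <- function(x, ...) {
  cat(sprintf(
    "SampEn(m = %d, r = %g, tau = %d, N = %d): %s (A = %d, B = %d, max = %.2f)\n",
    x$m, x$r, x$tau, x$n,
    if (is.na(x$value)) "undefined (no matches)" else sprintf("%.4f", x$value),
    as.integer(x$A), as.integer(x$B), x$max_value
  ))
  invisible(x)
}

#' Maximum attainable Sample Entropy
#'
#' The largest SampEn observable for a record of length `N` with template
#' length `m` and delay `tau`: `log(N - m*tau - 1) + log(N - m*tau) - log(2)`
#' (nats), reached when a single length-m pair matches out of all template
#' pairs. At `tau = 1` this reduces to the familiar
#' `log(N - m - 1) + log(N - m) - log(2)` bound.
#'
#' @param N record length; must exceed `m * tau + 1`.
#' @param m template length.
#' @param tau time delay.
#' @return the bound in nats.
#' @export
#' @examples
#' max_sampen(1000, 1, 1)  # 13.12 to two decimals
max_sampen <- function(N, m = 1, tau = 1) {
  if (any(N <= m * tau + 1)) stop("need N > m * tau + 1")
  log(N - m * tau - 1) + log(N - m * tau) - log(2)
}

#' Normalize a SampEn value by its maximum-entropy bound
#'
#' Maps a SampEn estimate onto the 0-1 scale, where 0 is complete
#' regularity and 1 complete randomness, by dividing by [max_sampen()].
#' Intended for comparing records of different lengths, with the caveat
#' that for stochastic series the bound grows with `N`, so longer records
#' of the same process score systematically lower.
#'
#' @param value SampEn estimate (nats).
#' @param N,m,tau the hyperparameters the estimate was computed with.
#' @return normalized value in `[0, 1]` for defined inputs.
#' @export
normalize_sampen <- function(value, N, m = 1, tau = 1) {
  value / max_sampen(N, m, tau)
}
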