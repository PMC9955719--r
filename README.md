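# stochent

Tools for applying Sample Entropy to temporally correlated stochastic time
series — the kind produced by stride-interval, center-of-pressure, and other
cycle-to-cycle biomechanical measurements.

Such series are well described by the fractional Gaussian noise / fractional
Brownian motion (fGn/fBm) model, indexed by a scaling exponent α: α ∈ (0, 1)
for stationary fGn, α ∈ (1, 2) for nonstationary fBm, α = 0.5 uncorrelated
noise, α = 1 the 1/f boundary. The package provides:

- **Exact simulation** of ARFIMA(0,d,0) fractional noise (α = d + 0.5) and its
  cumulative-sum fBm counterpart: Durbin–Levinson or circulant-embedding
  sampling from the closed-form autocovariance, standardized, seeded, and
  reproducible (`simulate_fgn()`, `simulate_alpha()`).
- **Whittle estimation and classification**: the profile Whittle likelihood
  with spectral shape |2 sin(λ/2)|^(−2d) estimates d; boundary pile-up of the
  bounded fit signals nonstationarity, triggering the difference-and-refit
  procedure that returns α on either side of the boundary
  (`fit_d()`, `classify_and_estimate()`).
- **Evenly spaced average DFA** as the complementary α estimator
  (`dfa_alpha()`).
- **SampEn(m, r, τ)** = −ln(A/B), where B counts template pairs of length m
  within tolerance r·SD (Chebyshev distance, no self-matches, delay τ) and A
  the pairs still matching at length m + 1; plus the maximum-entropy bound
  ln(N−mτ−1) + ln(N−mτ) − ln 2 and 0–1 normalization
  (`sampen()`, `max_sampen()`, `normalize_sampen()`).
- **Outlier tools**: additive-spike injection, conservative scaled-MAD
  detection (5 × 1.4826 × MAD), tolerance adjustment by the SD ratio, removal,
  and classification-guided removal that detects spikes on the increments of
  nonstationary series (`contaminate()`, `detect_outliers()`, `adjusted_r()`,
  `remove_outliers()`, `clean_with_classification()`).
- **A study harness** rerunning the estimation, classification, outlier,
  discrimination, and normalization simulation designs at configurable scale
  as tidy per-replicate tables (`run_estimation_study()` and friends,
  `summarize_study()`).

## A worked example

```r
library(stochent)

s <- simulate_alpha(0.8, 1000, seed = 42)  # persistent fGn, alpha = 0.8
classify_and_estimate(s$values)
#> Whittle ARFIMA(0,d,0) fit: stationary, alpha_hat = 0.794 (d_hat = 0.294)
sampen(s$values)
#> SampEn(m = 1, r = 0.25, tau = 1, N = 1000): 1.8963 (A = 10491, B = 69883, max = 13.12)

ct <- contaminate(s$values, seed = 43)     # spike 1% of points at 3x range
sampen(ct$values)$value                    # tolerance inflated -> biased low
#> [1] 1.127176
out <- clean_with_classification(ct$values)
out
#> Cleaning (classify_remove, stationary): removed 9 of 1000 observations
sampen(out$cleaned_values)$value           # bias removed
#> [1] 1.89207
```

The entropy drops by a third when nine of a thousand points are spiked — the
spikes inflate the SD, widen the match tolerance, and flood the match counts —
and returns to within 0.3% of the clean value after scaled-MAD removal.

A thin command-line front end over the same functions ships in
`inst/cli/stochent` (subcommands `simulate`, `fit`, `dfa`, `entropy`,
`clean`, each emitting JSON).

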