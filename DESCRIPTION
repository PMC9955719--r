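Package: stochent
Title: Sample Entropy for Temporally Correlated Stochastic Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for applying Sample Entropy to temporally correlated
    stochastic time series spanning the fractional Gaussian noise /
    fractional Brownian motion model. Provides exact simulation of
    ARFIMA(0,d,0) fractional noise (Durbin-Levinson and circulant
    embedding), Whittle-likelihood estimation of the fractional
    difference order with difference-and-refit stationarity
    classification, evenly spaced average detrended fluctuation
    analysis, SampEn(m, r, tau) with its maximum-entropy normalization,
    outlier injection and scaled-MAD cleaning procedures (including
    classification-guided removal for nonstationary series), and a
    simulation-study harness producing tidy per-replicate tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
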