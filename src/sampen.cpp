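#include <Rcpp.h>
using namespace Rcpp;

// Pairwise template-match counts for SampEn(m, r, tau).
//
// Templates u_i = (x_i, x_{i+tau}, ..., x_{i+(m-1)tau}), i = 1..N - m*tau.
// B counts unordered pairs i < j whose length-m templates are within `tol`
// in Chebyshev (max-coordinate) distance; A counts the same pairs for the
// length-(m+1) templates over the same index range (the equal-count
// convention: both counts use i = 1..N - m*tau). No self-matches.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double tol, int tau) {
  const int n = x.size();
  const int nt = n - m * tau; // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k * tau] - x[j + k * tau]);
        if (dd > dmax) dmax = dd;
        if (dmax > tol) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double dd = std::fabs(x[i + m * tau] - x[j + m * tau]);
      if (dd <= tol && dmax <= tol) A += 1.0;
    }
  }
  return NumericVector::create(A, B);
}
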