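#include <Rcpp.h>
#include <cmath>

// Sample entropy by direct template matching (Chebyshev distance).
// Counts pairs of length-m templates within tolerance r (B) and the
// subset whose (m+1)-th points also match (A); SampEn = -log(A/B).
// Templates start at 0..n-m-1 so the m+1 extension always exists;
// self-matches are excluded.
// [[Rcpp::export]]
double sampen_cpp(Rcpp::NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m; // number of templates
  if (nt < 2) return NA_REAL;
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
    }
  }
  if (B == 0 || A == 0) return NA_REAL;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}
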