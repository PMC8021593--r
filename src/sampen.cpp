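#include <Rcpp.h>
#include <cmath>

// Sample entropy, SampEn(m, r): -log(A/B) with B the number of template
// pairs matching at length m (Chebyshev distance <= r) and A the number
// still matching at length m+1.  Self-matches are excluded.  Returns 0 for
// degenerate inputs (constant signal, or no matches at either length).
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(Rcpp::NumericVector xv, int m, double r) {
  const int n = xv.size();
  const double* x = xv.begin();
  if (n <= m + 1 || r <= 0.0) return 0.0;
  long long B = 0, A = 0;
  const int nm = n - m;  // number of length-m templates with an extension
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
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
  if (B == 0 || A == 0) return 0.0;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}
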