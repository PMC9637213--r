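#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy template counts: B = m-length matches, A = (m+1)-length
// matches, Chebyshev distance <= r, self-matches excluded.  O(n^2).
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  int n = x.size();
  long long A = 0, B = 0;
  int nm = n - m;  // number of m-length templates
  for (int i = 0; i < nm; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        ++B;
        if (i + m < n && j + m < n) {
          double dm = std::fabs(x[i + m] - x[j + m]);
          if (std::max(d, dm) <= r) ++A;
        }
      }
    }
  }
  return NumericVector::create((double)A, (double)B);
}
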