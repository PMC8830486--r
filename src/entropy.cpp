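#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy.  Templates of length m (and
// their m+1 extensions) built with spacing `delay`; Chebyshev distance;
// matches are pairs i < j (self-matches excluded) with distance <= r.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r, int delay) {
  const int N = x.size();
  const int nt = N - m * delay; // both m- and (m+1)-length windows defined
  if (nt < 2) stop("series too short for the requested template length");
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dm = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k * delay] - x[j + k * delay]);
        if (d > dm) dm = d;
        if (dm > r) break;
      }
      if (dm <= r) {
        B += 1.0;
        double d = std::fabs(x[i + m * delay] - x[j + m * delay]);
        if (d <= r) A += 1.0; // max(dm, d) <= r
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B, _["n_templates"] = nt);
}
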