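#include <Rcpp.h>
using namespace Rcpp;

// Template-matching pair counts for sample entropy (Richman-Moorman
// convention): B = number of ordered pairs i < j of length-m templates whose
// Chebyshev distance is strictly below r; A = the same pairs extended by one
// point. Both counts range over the same N - m start positions, so the last
// length-m template is excluded and A/B is a conditional probability.
// Self-matches are excluded by construction (i < j).
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // template start positions for both lengths
  if (m < 1) stop("m must be >= 1");
  if (nt < 2) stop("series too short for m = %d: need length > m + 1", m);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d < r) {
        B += 1.0;
        if (std::fabs(x[i + m] - x[j + m]) < r) A += 1.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
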