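#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Template-match pair counts for sample entropy. Vectors X_m(i) for
// i = 1..N-m are compared under the Chebyshev (max-component) distance with
// strict tolerance d < r, self-matches excluded. B counts m-point matches,
// A counts (m+1)-point matches over the same index range, so the ratio of
// the averaged per-template probabilities equals A/B and
// SampEn = -ln(A/B).
// [[Rcpp::export(name = ".sampen_counts_cpp")]]
List sampen_counts_cpp(NumericVector u, int m, double r) {
  int N = u.size();
  int nv = N - m;              // number of m-length templates considered
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nv; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      double dmax = 0.0;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(u[i + k] - u[j + k]);
        if (d > dmax) dmax = d;
        if (dmax >= r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      double d = std::fabs(u[i + m] - u[j + m]);
      if (d > dmax) dmax = d;
      if (dmax < r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
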