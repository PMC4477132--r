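#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Strict local extrema by sign change of the first difference; a flat
// plateau contributes a single extremum at its midpoint (rounded down).
// Indices returned are 0-based; callers add 1 for R.
static void extrema_scan(const double* x, int n,
                         std::vector<int>& maxima, std::vector<int>& minima) {
  int last_sign = 0;
  int plateau_start = 0; // first index of the current run of equal values
  for (int j = 0; j + 1 < n; ++j) {
    double d = x[j + 1] - x[j];
    int s = (d > 0) - (d < 0);
    if (s == 0) continue;
    if (last_sign != 0 && s != last_sign) {
      int idx = (plateau_start + j) / 2;
      if (last_sign > 0) maxima.push_back(idx); else minima.push_back(idx);
    }
    last_sign = s;
    plateau_start = j + 1;
  }
}

// [[Rcpp::export(name = ".find_extrema_cpp")]]
List find_extrema_cpp(NumericVector x) {
  std::vector<int> mx, mn;
  extrema_scan(x.begin(), x.size(), mx, mn);
  IntegerVector rmx(mx.size()), rmn(mn.size());
  for (size_t i = 0; i < mx.size(); ++i) rmx[i] = mx[i] + 1;
  for (size_t i = 0; i < mn.size(); ++i) rmn[i] = mn[i] + 1;
  return List::create(_["maxima"] = rmx, _["minima"] = rmn);
}

// Sign changes over the subsequence of nonzero samples; a zero sample takes
// the sign of the next nonzero one, so it never adds a crossing of its own.
// [[Rcpp::export(name = ".zero_crossings_cpp")]]
int zero_crossings_cpp(NumericVector x) {
  int n = x.size(), count = 0, last = 0;
  for (int i = 0; i < n; ++i) {
    int s = (x[i] > 0) - (x[i] < 0);
    if (s == 0) continue;
    if (last != 0 && s != last) ++count;
    last = s;
  }
  return count;
}

// Natural cubic spline through (t, y), evaluated at integer grid 1..n.
// Second derivatives from the standard tridiagonal system (Thomas solve);
// linear for two knots, constant for one.
static void natural_spline_eval(const std::vector<double>& t,
                                const std::vector<double>& y,
                                int n, std::vector<double>& out) {
  int m = (int)t.size();
  out.assign(n, 0.0);
  if (m == 1) { for (int i = 0; i < n; ++i) out[i] = y[0]; return; }
  if (m == 2) {
    double slope = (y[1] - y[0]) / (t[1] - t[0]);
    for (int i = 0; i < n; ++i) out[i] = y[0] + slope * ((i + 1) - t[0]);
    return;
  }
  std::vector<double> h(m - 1);
  for (int k = 0; k < m - 1; ++k) h[k] = t[k + 1] - t[k];
  // tridiagonal system for interior second derivatives M[1..m-2]
  std::vector<double> M(m, 0.0), diag(m, 0.0), rhs(m, 0.0), sub(m, 0.0), sup(m, 0.0);
  for (int k = 1; k < m - 1; ++k) {
    sub[k] = h[k - 1];
    diag[k] = 2.0 * (h[k - 1] + h[k]);
    sup[k] = h[k];
    rhs[k] = 6.0 * ((y[k + 1] - y[k]) / h[k] - (y[k] - y[k - 1]) / h[k - 1]);
  }
  for (int k = 2; k < m - 1; ++k) {
    double w = sub[k] / diag[k - 1];
    diag[k] -= w * sup[k - 1];
    rhs[k] -= w * rhs[k - 1];
  }
  for (int k = m - 2; k >= 1; --k) {
    M[k] = (rhs[k] - sup[k] * (k + 1 <= m - 2 ? M[k + 1] : 0.0)) / diag[k];
  }
  int seg = 0;
  for (int i = 0; i < n; ++i) {
    double xv = i + 1;
    while (seg < m - 2 && t[seg + 1] < xv) ++seg;
    // clamp: with mirrored end knots xv stays inside [t0, t_{m-1}]; if not,
    // the end segment's cubic extends linearly enough for our use
    double hk = h[seg];
    double a = (t[seg + 1] - xv) / hk, b = (xv - t[seg]) / hk;
    out[i] = a * y[seg] + b * y[seg + 1] +
      ((a * a * a - a) * M[seg] + (b * b * b - b) * M[seg + 1]) * (hk * hk) / 6.0;
  }
}

// Mirror-extend extrema knots across both signal ends (up to `nref` knots
// reflected at each end), then fit the envelope spline.
static void build_knots(const std::vector<int>& idx, const double* x, int n,
                        int nref, std::vector<double>& t, std::vector<double>& y) {
  int m = (int)idx.size();
  int kref = std::min(nref, m);
  t.clear(); y.clear();
  for (int k = kref - 1; k >= 0; --k) {       // reflect about t = 1
    t.push_back(2.0 * 1.0 - (idx[k] + 1));
    y.push_back(x[idx[k]]);
  }
  for (int k = 0; k < m; ++k) { t.push_back(idx[k] + 1.0); y.push_back(x[idx[k]]); }
  for (int k = 0; k < kref; ++k) {            // reflect about t = n
    t.push_back(2.0 * n - (idx[m - 1 - k] + 1.0));
    y.push_back(x[idx[m - 1 - k]]);
  }
}

static bool envelope_mean_core(const double* x, int n, int min_extrema,
                               std::vector<double>& mean_env) {
  std::vector<int> mx, mn;
  extrema_scan(x, n, mx, mn);
  if ((int)mx.size() < min_extrema || (int)mn.size() < min_extrema) return false;
  std::vector<double> t, y, upper, lower;
  build_knots(mx, x, n, 2, t, y);
  natural_spline_eval(t, y, n, upper);
  build_knots(mn, x, n, 2, t, y);
  natural_spline_eval(t, y, n, lower);
  mean_env.assign(n, 0.0);
  for (int i = 0; i < n; ++i) mean_env[i] = 0.5 * (upper[i] + lower[i]);
  return true;
}

// [[Rcpp::export(name = ".envelope_mean_cpp")]]
SEXP envelope_mean_cpp(NumericVector x, int min_extrema) {
  std::vector<double> env;
  if (!envelope_mean_core(x.begin(), x.size(), min_extrema, env))
    return R_NilValue;
  return wrap(env);
}

static bool is_imf_core(const double* x, int n) {
  std::vector<int> mx, mn;
  extrema_scan(x, n, mx, mn);
  int nz = 0, last = 0;
  for (int i = 0; i < n; ++i) {
    int s = (x[i] > 0) - (x[i] < 0);
    if (s == 0) continue;
    if (last != 0 && s != last) ++nz;
    last = s;
  }
  int ne = (int)(mx.size() + mn.size());
  return std::abs(ne - nz) <= 1;
}

// [[Rcpp::export(name = ".is_imf_cpp")]]
bool is_imf_cpp(NumericVector x) { return is_imf_core(x.begin(), x.size()); }

// One sifting pass: h <- h - envelope_mean(h) until the Cauchy criterion
// SD = sum((h_prev - h)^2) / sum(h_prev^2) < sd_threshold together with the
// IMF conditions, or max_iters, or the extrema are exhausted.
// [[Rcpp::export(name = ".sift_cpp")]]
List sift_cpp(NumericVector x, double sd_threshold, int max_iters, int min_extrema) {
  int n = x.size();
  std::vector<double> h(x.begin(), x.end()), env;
  std::string reason = "max_iters";
  int iters = 0;
  for (int it = 1; it <= max_iters; ++it) {
    if (!envelope_mean_core(h.data(), n, min_extrema, env)) {
      reason = "extrema_exhausted";
      break;
    }
    double num = 0.0, den = 0.0;
    for (int i = 0; i < n; ++i) {
      num += env[i] * env[i];        // h_prev - h_new = envelope mean
      den += h[i] * h[i];
      h[i] -= env[i];
    }
    iters = it;
    double sd = den > 0 ? num / den : 0.0;
    if (sd < sd_threshold && is_imf_core(h.data(), n)) {
      reason = "converged";
      break;
    }
  }
  return List::create(_["h"] = wrap(h), _["iterations"] = iters,
                      _["reason"] = reason);
}
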