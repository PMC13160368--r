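#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Exact hull of the conformal accept region at one time point (see the R
// documentation in conformal.R). r_i are the fixed parts of the calibration
// residuals, w_i the augmented-smoother weights of the new observation,
// cnew its smoothed point prediction, k the lower-quantile index. The count
// of scores |r_i - w_i y| strictly below |y - cnew| is piecewise constant
// between the roots of (r_i - w_i y)^2 = (y - cnew)^2; segments with count
// <= k - 1 are accepted.
// [[Rcpp::export]]
NumericVector exact_hull_cpp(NumericVector r, NumericVector w, double cnew,
                             int k) {
  int m = r.size();
  std::vector<double> roots;
  roots.reserve(2 * m);
  for (int i = 0; i < m; ++i) {
    double a2 = w[i] * w[i] - 1.0;
    double b2 = -2.0 * (r[i] * w[i] - cnew);
    double c2 = r[i] * r[i] - cnew * cnew;
    if (std::fabs(a2) > 1e-14) {
      double disc = b2 * b2 - 4.0 * a2 * c2;
      if (disc >= 0.0) {
        double sq = std::sqrt(disc);
        roots.push_back((-b2 + sq) / (2.0 * a2));
        roots.push_back((-b2 - sq) / (2.0 * a2));
      }
    } else if (std::fabs(b2) > 1e-14) {
      roots.push_back(-c2 / b2);
    }
  }
  if (roots.empty()) return NumericVector::create(cnew, cnew);
  std::sort(roots.begin(), roots.end());

  int R = roots.size();
  double lo = NA_REAL, hi = NA_REAL;
  bool found = false;
  for (int s = 0; s <= R; ++s) {
    double y;
    if (s == 0) y = roots[0] - 1.0;
    else if (s == R) y = roots[R - 1] + 1.0;
    else {
      if (roots[s] - roots[s - 1] < 1e-300) continue;
      y = 0.5 * (roots[s - 1] + roots[s]);
    }
    double snew = std::fabs(y - cnew);
    int cnt = 0;
    for (int i = 0; i < m; ++i) {
      if (std::fabs(r[i] - w[i] * y) < snew) ++cnt;
    }
    if (cnt <= k - 1) {
      // unbounded outer segments cannot be accepted in practice (the new
      // score outgrows every calibration score); clamp to the root range
      double seg_lo = (s == 0) ? roots[0] : roots[s - 1];
      double seg_hi = (s == R) ? roots[R - 1] : roots[s];
      if (!found) { lo = seg_lo; hi = seg_hi; found = true; }
      else { lo = std::min(lo, seg_lo); hi = std::max(hi, seg_hi); }
    }
  }
  if (!found) return NumericVector::create(cnew, cnew);
  return NumericVector::create(lo, hi);
}
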