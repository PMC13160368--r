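#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Dynamic-programming alignment of SRSF q2 to SRSF q1 on a common uniform
// grid. The search space is the set of piecewise-linear monotone lattice
// paths from (1,1) to (T,T) whose elementary steps (di, dj) are coprime
// pairs with 1 <= di, dj <= nbhd, i.e. local slopes in [1/nbhd, nbhd].
//
// Edge cost for a step from node (a, b) to node (i, j), with slope
// s = (t_j - t_b) / (t_i - t_a): trapezoidal quadrature of
//   (q1(t) - q2(gamma(t)) * sqrt(s))^2
// over the fine-grid points t_a, ..., t_i, with gamma linear on the segment
// and q2 evaluated by linear interpolation. Ties between equal-cost
// predecessors break toward the step closest to the identity diagonal
// (smallest |di - dj|, then smallest di), which makes the optimum
// deterministic and returns the identity path for equal inputs.

static inline double edge_cost(const double* q1, const double* q2,
                               int a, int b, int di, int dj, int T,
                               double rs, double h) {
  // gamma(t_k) as a grid index is b + dj*o/di for offsets o = 0..di; the
  // integer and fractional parts come from integer division, so the linear
  // interpolation of q2 needs no floor() calls.
  double acc = 0.0;
  int i = a + di;
  for (int o = 0; o <= di; ++o) {
    int num = dj * o;
    int fl = b + num / di;
    double w = (double)(num % di) / (double)di;
    double q2v = (fl >= T - 1) ? q2[T - 1] : q2[fl] * (1.0 - w) + q2[fl + 1] * w;
    double diff = q1[a + o] - q2v * rs;
    double wt = (o == 0 || o == di) ? 0.5 : 1.0;
    acc += wt * diff * diff;
  }
  (void)i;
  return acc * h;
}

// [[Rcpp::export]]
List dp_align_srsf(NumericVector q1, NumericVector q2, int nbhd = 7) {
  int T = q1.size();
  if (q2.size() != T || T < 2)
    stop("SRSFs must share a common grid with at least 2 points");

  // Coprime step set.
  std::vector<int> di, dj;
  for (int p = 1; p <= nbhd; ++p) {
    for (int q = 1; q <= nbhd; ++q) {
      int a = p, b = q;
      while (b) { int t = a % b; a = b; b = t; }
      if (a == 1) { di.push_back(p); dj.push_back(q); }
    }
  }
  int S = di.size();
  std::vector<double> rs(S);
  for (int s = 0; s < S; ++s) rs[s] = std::sqrt((double)dj[s] / (double)di[s]);

  const double* p1 = q1.begin();
  const double* p2 = q2.begin();
  double h = 1.0 / (double)(T - 1);

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> E((size_t)T * T, INF);
  std::vector<int> pred((size_t)T * T, -1);
  E[0] = 0.0;

  for (int i = 1; i < T; ++i) {
    for (int j = 1; j < T; ++j) {
      double best = INF;
      int best_s = -1, best_dev = 0;
      for (int s = 0; s < S; ++s) {
        int a = i - di[s], b = j - dj[s];
        if (a < 0 || b < 0) continue;
        double ea = E[(size_t)a * T + b];
        if (!std::isfinite(ea)) continue;
        double c = ea + edge_cost(p1, p2, a, b, di[s], dj[s], T, rs[s], h);
        int dev = std::abs(di[s] - dj[s]);
        if (c < best - 1e-12 ||
            (std::abs(c - best) <= 1e-12 &&
             (dev < best_dev || (dev == best_dev && best_s >= 0 &&
                                 di[s] < di[best_s])))) {
          best = c;
          best_s = s;
          best_dev = dev;
        }
      }
      E[(size_t)i * T + j] = best;
      pred[(size_t)i * T + j] = best_s;
    }
  }

  // Backtrack the optimal path.
  std::vector<int> pi, pj;
  int i = T - 1, j = T - 1;
  pi.push_back(i); pj.push_back(j);
  while (i > 0 || j > 0) {
    int s = pred[(size_t)i * T + j];
    if (s < 0) stop("dynamic program failed to reach the origin");
    i -= di[s]; j -= dj[s];
    pi.push_back(i); pj.push_back(j);
  }

  // Piecewise-linear warping through the path nodes, sampled on the grid.
  int M = pi.size();
  NumericVector gx(M), gy(M);
  for (int k = 0; k < M; ++k) {
    gx[k] = (double)pi[M - 1 - k] / (double)(T - 1);
    gy[k] = (double)pj[M - 1 - k] / (double)(T - 1);
  }
  NumericVector gamma(T);
  int seg = 0;
  for (int k = 0; k < T; ++k) {
    double t = (double)k / (double)(T - 1);
    while (seg < M - 2 && gx[seg + 1] < t) ++seg;
    double w = (t - gx[seg]) / (gx[seg + 1] - gx[seg]);
    gamma[k] = gy[seg] * (1.0 - w) + gy[seg + 1] * w;
  }
  gamma[0] = 0.0;
  gamma[T - 1] = 1.0;

  return List::create(Named("gamma") = gamma,
                      Named("value") = E[(size_t)(T - 1) * T + (T - 1)],
                      Named("path_i") = gx,
                      Named("path_j") = gy);
}
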