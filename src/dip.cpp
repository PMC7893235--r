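// Hartigans' dip statistic.
//
// The dip of an empirical CDF F_n is the smallest sup-norm distance to any
// unimodal CDF (convex below the mode, concave above, with an atom allowed
// at the mode). Writing lo_g and hi_g for the values of F_n just before and
// at the g-th distinct data value, a CDF G continuous at x_g must satisfy
// the "gate" hi_g - d <= G(x_g) <= lo_g + d; at the mode the gate splits
// into a left-limit gate centred at lo_g and a value gate centred at hi_g,
// coupled by G(m-) <= G(m+). For a given d and mode position the convex
// branch exists iff the forced minimal values F_j (propagated by the
// minimal exit slopes the gates impose on a convex nondecreasing chain)
// stay inside the gates, and the two branches are compatible iff the
// minimal attainable left-limit does not exceed the maximal attainable
// mode value (mirror computation). The dip is found by bisection on d.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct DipWork {
  // per distinct value: forced minimal chain value and exit slope
  std::vector<double> F, S, minEnd;
  std::vector<char> prefOK;
};

// convex nondecreasing chain through gates [hi_j - d, lo_j + d] at X_j.
// Fills w.prefOK[t] = gates 0..t-1 are jointly satisfiable, and
// w.minEnd[t] = minimal attainable value of the chain extension at X_t
// over chains through gates 0..t-1 (ignoring X_t's own gate).
static void chainScan(const std::vector<double>& X,
                      const std::vector<double>& lo,
                      const std::vector<double>& hi,
                      double d, DipWork& w) {
  const int G = (int)X.size();
  const double tol = 1e-12;
  w.F.assign(G, 0.0); w.S.assign(G, 0.0);
  w.minEnd.assign(G, -1e300); w.prefOK.assign(G + 1, 1);
  bool ok = true;
  for (int j = 0; j < G; ++j) {
    double A = hi[j] - d, B = lo[j] + d;
    double ext = -1e300;                   // forced extension, own gate aside
    for (int i = 0; i < j; ++i) {
      double cand = w.F[i] + w.S[i] * (X[j] - X[i]);
      if (cand > ext) ext = cand;
    }
    w.minEnd[j] = ext;
    double Fj = std::max(ext, A);
    if (A > B + tol || Fj > B + tol) ok = false;
    w.prefOK[j + 1] = ok ? 1 : 0;
    w.F[j] = Fj;
    double Sj = 0.0;
    for (int h = 0; h < j; ++h) {
      double s = (w.F[j] - (lo[h] + d)) / (X[j] - X[h]);
      if (s > Sj) Sj = s;
    }
    w.S[j] = Sj;
  }
}

static bool dipFeasible(const std::vector<double>& X,
                        const std::vector<double>& lo,
                        const std::vector<double>& hi,
                        double d, DipWork& wl, DipWork& wr,
                        const std::vector<double>& Xr,
                        const std::vector<double>& lor,
                        const std::vector<double>& hir) {
  const int G = (int)X.size();
  const double tol = 1e-12;
  chainScan(X, lo, hi, d, wl);
  chainScan(Xr, lor, hir, d, wr);
  for (int t = 0; t < G; ++t) {
    if (!wl.prefOK[t]) break;              // prefixes only get worse
    int tr = G - 1 - t;                    // position of t in mirrored scan
    if (!wr.prefOK[tr]) continue;
    // left-limit gate at the mode, centred lo_t
    double minL = lo[t] - d;
    if (t > 0 && wl.minEnd[t] > minL) minL = wl.minEnd[t];
    if (minL > lo[t] + d + tol) continue;
    // mode-value gate, centred hi_t; mirrored minimal end = -max start
    double maxR = hi[t] + d;
    if (tr > 0 && -wr.minEnd[tr] < maxR) maxR = -wr.minEnd[tr];
    if (maxR < hi[t] - d - tol) continue;
    if (minL <= maxR + tol) return true;
  }
  return false;
}

static double dipSorted(const std::vector<double>& x) {
  const int n = (int)x.size();
  const double floorv = 0.5 / n;
  std::vector<double> X, lo, hi;
  int i = 0;
  while (i < n) {
    int j = i;
    while (j < n && x[j] == x[i]) ++j;
    X.push_back(x[i]);
    lo.push_back((double)i / n);
    hi.push_back((double)j / n);
    i = j;
  }
  const int G = (int)X.size();
  if (G == 1) return floorv;
  // mirrored arrays: (x, F) -> (-x, -F) turns the concave branch into a
  // convex chain with gates of the same form
  std::vector<double> Xr(G), lor(G), hir(G);
  for (int g = 0; g < G; ++g) {
    Xr[g] = -X[G - 1 - g];
    lor[g] = -hi[G - 1 - g];
    hir[g] = -lo[G - 1 - g];
  }
  DipWork wl, wr;
  double a = floorv * 0.5, b = 0.2500001;
  if (dipFeasible(X, lo, hi, a, wl, wr, Xr, lor, hir)) return floorv;
  for (int it = 0; it < 50; ++it) {
    double mid = 0.5 * (a + b);
    if (dipFeasible(X, lo, hi, mid, wl, wr, Xr, lor, hir)) b = mid;
    else a = mid;
  }
  double d = b;
  if (d < floorv) d = floorv;
  if (d > 0.25) d = 0.25;
  return d;
}

// [[Rcpp::export]]
double dip_cpp(NumericVector x) {
  std::vector<double> v(x.begin(), x.end());
  std::sort(v.begin(), v.end());
  return dipSorted(v);
}

// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int nmc) {
  NumericVector out(nmc);
  std::vector<double> v(n);
  for (int m = 0; m < nmc; ++m) {
    for (int i = 0; i < n; ++i) v[i] = R::unif_rand();
    std::sort(v.begin(), v.end());
    out[m] = dipSorted(v);
  }
  return out;
}
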