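#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Semi-axis lookup for the sign-selected octant of a piecewise ellipsoid.
// ax = (a_plus, a_minus, b_plus, b_minus, c_plus, c_minus).
static inline void octant_axes(double x, double y, double z,
                               const double *ax,
                               double &a, double &b, double &c) {
  a = (x >= 0.0) ? ax[0] : ax[1];
  b = (y >= 0.0) ? ax[2] : ax[3];
  c = (z >= 0.0) ? ax[4] : ax[5];
}

static inline bool inside_pe_one(double x, double y, double z, const double *ax) {
  double a, b, c;
  octant_axes(x, y, z, ax, a, b, c);
  double u = x / a, v = y / b, w = z / c;
  return u * u + v * v + w * w <= 1.0;
}

// [[Rcpp::export]]
LogicalVector cpp_inside_pe(NumericMatrix pts, NumericVector ax) {
  const int n = pts.nrow();
  LogicalVector out(n);
  const double *a = ax.begin();
  for (int i = 0; i < n; ++i)
    out[i] = inside_pe_one(pts(i, 0), pts(i, 1), pts(i, 2), a);
  return out;
}

// Uniform points inside a piecewise ellipsoid by rejection from its bounding
// box.  Acceptance rate is pi/6 for every parameter set, so this cannot
// degenerate.  Uses R's RNG stream.
// [[Rcpp::export]]
NumericMatrix cpp_sample_csr_pe(int n, NumericVector ax) {
  NumericMatrix out(n, 3);
  const double *a = ax.begin();
  const double lox = -a[1], hix = a[0];
  const double loy = -a[3], hiy = a[2];
  const double loz = -a[5], hiz = a[4];
  int got = 0;
  while (got < n) {
    double x = R::runif(lox, hix);
    double y = R::runif(loy, hiy);
    double z = R::runif(loz, hiz);
    if (inside_pe_one(x, y, z, a)) {
      out(got, 0) = x;
      out(got, 1) = y;
      out(got, 2) = z;
      ++got;
    }
  }
  return out;
}

// Nearest-neighbour Euclidean distance from each row of `ref` to the point
// set `pat`.  Brute force: pattern sizes here are tens to hundreds.
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericMatrix ref, NumericMatrix pat) {
  const int m = ref.nrow(), n = pat.nrow();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const double x = ref(i, 0), y = ref(i, 1), z = ref(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < n; ++j) {
      const double dx = x - pat(j, 0);
      const double dy = y - pat(j, 1);
      const double dz = z - pat(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Strict empirical CDF: for each r in grid, fraction of d strictly below r.
// [[Rcpp::export]]
NumericVector cpp_ecdf_strict(NumericVector d, NumericVector grid) {
  std::vector<double> ds(d.begin(), d.end());
  std::sort(ds.begin(), ds.end());
  const int g = grid.size();
  const double n = static_cast<double>(ds.size());
  NumericVector out(g);
  for (int i = 0; i < g; ++i) {
    out[i] = (std::lower_bound(ds.begin(), ds.end(), grid[i]) - ds.begin()) / n;
  }
  return out;
}

// Batched null F-curves for a piecewise-ellipsoid region: n_rep independent
// CSR patterns of exactly n_pts points, each scored against its own fresh set
// of n_ref uniform reference points.  Returns an n_rep x length(grid) matrix.
// This is the inner loop of envelope tests and the SDI, kept in C++ because a
// single power or SDI study evaluates it hundreds of thousands of times.
// [[Rcpp::export]]
NumericMatrix cpp_null_fcurves_pe(NumericVector ax, int n_pts, int n_rep,
                                  int n_ref, NumericVector grid) {
  const int g = grid.size();
  NumericMatrix out(n_rep, g);
  const double *a = ax.begin();
  const double lox = -a[1], hix = a[0];
  const double loy = -a[3], hiy = a[2];
  const double loz = -a[5], hiz = a[4];
  std::vector<double> px(n_pts), py(n_pts), pz(n_pts);
  std::vector<double> nnd(n_ref);
  for (int r = 0; r < n_rep; ++r) {
    int got = 0;
    while (got < n_pts) {
      double x = R::runif(lox, hix);
      double y = R::runif(loy, hiy);
      double z = R::runif(loz, hiz);
      if (inside_pe_one(x, y, z, a)) {
        px[got] = x; py[got] = y; pz[got] = z;
        ++got;
      }
    }
    got = 0;
    while (got < n_ref) {
      double x = R::runif(lox, hix);
      double y = R::runif(loy, hiy);
      double z = R::runif(loz, hiz);
      if (!inside_pe_one(x, y, z, a)) continue;
      double best = R_PosInf;
      for (int j = 0; j < n_pts; ++j) {
        const double dx = x - px[j];
        const double dy = y - py[j];
        const double dz = z - pz[j];
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
      nnd[got] = std::sqrt(best);
      ++got;
    }
    std::sort(nnd.begin(), nnd.end());
    const double denom = static_cast<double>(n_ref);
    for (int i = 0; i < g; ++i) {
      out(r, i) =
          (std::lower_bound(nnd.begin(), nnd.end(), grid[i]) - nnd.begin()) /
          denom;
    }
  }
  return out;
}

// Maximum pairwise distance among rows of pts.
// [[Rcpp::export]]
List cpp_max_pairwise(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = -1.0;
  int bi = 0, bj = 0;
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = x - pts(j, 0);
      const double dy = y - pts(j, 1);
      const double dz = z - pts(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) {
        best = d2;
        bi = i;
        bj = j;
      }
    }
  }
  return List::create(_["dist"] = std::sqrt(best), _["i"] = bi + 1,
                      _["j"] = bj + 1);
}
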