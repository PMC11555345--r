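#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pentadiagonal LDL^T solve of (diag(w) + H) z = w*y, where H is the
// second-difference penalty lam * D'D stored as three bands. Bandwidth
// 2 keeps the factorization O(N), which is what makes per-pixel
// baseline correction of a full cube feasible.
static void penta_solve(const std::vector<double>& d0,
                        const std::vector<double>& d1,
                        const std::vector<double>& d2,
                        const std::vector<double>& b,
                        std::vector<double>& z) {
  int n = d0.size();
  std::vector<double> D(n), L1(n, 0.0), L2(n, 0.0), u(n);
  for (int i = 0; i < n; ++i) {
    double l1 = (i >= 1) ? d1[i - 1] : 0.0;   // A[i, i-1]
    double l2 = (i >= 2) ? d2[i - 2] : 0.0;   // A[i, i-2]
    if (i >= 2) L2[i] = l2 / D[i - 2];
    if (i >= 1) {
      double t = l1;
      if (i >= 2) t -= L2[i] * D[i - 2] * L1[i - 1];
      L1[i] = t / D[i - 1];
    }
    double di = d0[i];
    if (i >= 1) di -= L1[i] * L1[i] * D[i - 1];
    if (i >= 2) di -= L2[i] * L2[i] * D[i - 2];
    D[i] = di;
    double ui = b[i];
    if (i >= 1) ui -= L1[i] * u[i - 1];
    if (i >= 2) ui -= L2[i] * u[i - 2];
    u[i] = ui;
  }
  for (int i = n - 1; i >= 0; --i) {
    double zi = u[i] / D[i];
    if (i + 1 < n) zi -= L1[i + 1] * z[i + 1];
    if (i + 2 < n) zi -= L2[i + 2] * z[i + 2];
    z[i] = zi;
  }
}

static int arpls_one(const double* y, int n, double lam, double ratio_tol,
                     int max_iter, double* baseline, double* weights,
                     bool* converged) {
  // bands of lam * D'D (D = second difference operator)
  std::vector<double> h0(n), h1(n - 1), h2(n - 2);
  for (int i = 0; i < n; ++i) {
    double v = 6.0;
    if (i == 0 || i == n - 1) v = 1.0;
    else if (i == 1 || i == n - 2) v = 5.0;
    h0[i] = lam * v;
  }
  for (int i = 0; i < n - 1; ++i) {
    double v = (i == 0 || i == n - 2) ? -2.0 : -4.0;
    h1[i] = lam * v;
  }
  for (int i = 0; i < n - 2; ++i) h2[i] = lam;

  std::vector<double> w(n, 1.0), wt(n), d0(n), b(n), z(n, 0.0), d(n);
  double ymax = 0.0;
  for (int i = 0; i < n; ++i) ymax = std::max(ymax, std::fabs(y[i]));
  int it = 0;
  *converged = false;
  while (it < max_iter) {
    ++it;
    for (int i = 0; i < n; ++i) {
      d0[i] = h0[i] + w[i];
      b[i] = w[i] * y[i];
    }
    penta_solve(d0, h1, h2, b, z);
    int nneg = 0;
    double sum = 0.0, sum2 = 0.0;
    for (int i = 0; i < n; ++i) {
      d[i] = y[i] - z[i];
      if (d[i] < 0) { ++nneg; sum += d[i]; sum2 += d[i] * d[i]; }
    }
    if (nneg < 2) { *converged = true; break; }
    double m = sum / nneg;
    double s = std::sqrt((sum2 - nneg * m * m) / (nneg - 1));
    if (!std::isfinite(s) || s <= 2.2e-16 * std::max(ymax, 1.0)) {
      *converged = true; break;
    }
    double dw = 0.0, nw = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = 2.0 * (d[i] - (2.0 * s - m)) / s;
      if (e > 50.0) e = 50.0;
      wt[i] = 1.0 / (1.0 + std::exp(e));
      dw += (w[i] - wt[i]) * (w[i] - wt[i]);
      nw += w[i] * w[i];
    }
    bool done = std::sqrt(dw) / std::sqrt(nw) < ratio_tol;
    for (int i = 0; i < n; ++i) w[i] = wt[i];
    if (done) { *converged = true; break; }
  }
  for (int i = 0; i < n; ++i) {
    baseline[i] = z[i];
    weights[i] = w[i];
  }
  return it;
}

// [[Rcpp::export(name = ".arpls_engine")]]
List arpls_engine(NumericVector y, double lam, double ratio_tol,
                  int max_iter) {
  int n = y.size();
  NumericVector baseline(n), weights(n);
  bool conv = false;
  int it = arpls_one(REAL(y), n, lam, ratio_tol, max_iter,
                     REAL(baseline), REAL(weights), &conv);
  return List::create(_["baseline"] = baseline, _["weights"] = weights,
                      _["iterations"] = it, _["converged"] = conv);
}

// [[Rcpp::export(name = ".arpls_cube_engine")]]
NumericMatrix arpls_cube_engine(NumericMatrix flat, double lam,
                                double ratio_tol, int max_iter) {
  int npix = flat.nrow(), n = flat.ncol();
  NumericMatrix out(npix, n);
  std::vector<double> y(n), baseline(n), weights(n);
  for (int p = 0; p < npix; ++p) {
    for (int i = 0; i < n; ++i) y[i] = flat(p, i);
    bool conv = false;
    arpls_one(y.data(), n, lam, ratio_tol, max_iter, baseline.data(),
              weights.data(), &conv);
    for (int i = 0; i < n; ++i) out(p, i) = y[i] - baseline[i];
  }
  return out;
}
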