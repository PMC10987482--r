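// Penalized cubic B-spline regression: a cubic smoothing spline with an
// exact integrated-squared-second-derivative penalty, fit by banded normal
// equations. Used for the per-bead radial intensity profile, where the fit
// sits inside the bead-center optimization loop and must be fast.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Cubic B-spline basis with uniform breakpoints on [0, xmax], padded knots.
// k = n_intervals + 3 basis functions.
struct CubicBasis {
  arma::vec knots;   // full padded knot vector, length k + 4
  int k;
  double xmin, xmax;

  CubicBasis(double xmax_, double dk) : xmin(0.0), xmax(xmax_) {
    int m = std::max(2, (int)std::ceil(xmax_ / dk)); // intervals
    arma::vec br = arma::linspace(0.0, xmax_, m + 1);
    k = m + 3;
    knots.set_size(m + 7);
    for (int i = 0; i < 3; ++i) knots[i] = br[0];
    for (int i = 0; i <= m; ++i) knots[3 + i] = br[i];
    for (int i = 0; i < 3; ++i) knots[m + 4 + i] = br[m];
  }

  // index of knot interval containing x: largest i with knots[i] <= x,
  // clamped so that knots[i] < knots[i+1]
  int interval(double x) const {
    int lo = 3, hi = knots.n_elem - 5; // valid span indices
    if (x <= knots[lo]) return lo;
    if (x >= knots[hi + 1]) return hi;
    int i = lo;
    while (i < hi && x >= knots[i + 1]) ++i;
    return i;
  }

  // nonzero basis functions of degree p at x within span i (NURBS book A2.2);
  // fills N[0..p] = values of basis indices i-p .. i
  void basis_funs(int i, double x, int p, double* N) const {
    double left[4], right[4];
    N[0] = 1.0;
    for (int j = 1; j <= p; ++j) {
      left[j] = x - knots[i + 1 - j];
      right[j] = knots[i + j] - x;
      double saved = 0.0;
      for (int r = 0; r < j; ++r) {
        double den = right[r + 1] + left[j - r];
        double temp = (den > 0) ? N[r] / den : 0.0;
        N[r] = saved + right[r + 1] * temp;
        saved = left[j - r] * temp;
      }
      N[j] = saved;
    }
  }

  // values (deriv 0,1,2) of the 4 basis functions non-zero at x;
  // returns index of first one (i - 3).
  int basis(double x, int deriv, double* out) const {
    if (x < xmin) x = xmin;
    if (x > xmax) x = xmax;
    int i = interval(x);
    if (deriv == 0) {
      basis_funs(i, x, 3, out);
    } else if (deriv == 1) {
      double N3[3]; // degree-2 basis, indices i-2 .. i
      basis_funs(i, x, 2, N3);
      auto n3 = [&](int idx) -> double {
        int j = idx - (i - 2);
        return (j >= 0 && j <= 2) ? N3[j] : 0.0;
      };
      for (int j = 0; j < 4; ++j) {
        int bi = i - 3 + j;
        double den1 = knots[bi + 3] - knots[bi];
        double den2 = knots[bi + 4] - knots[bi + 1];
        double a = (den1 > 0) ? n3(bi) / den1 : 0.0;
        double b = (den2 > 0) ? n3(bi + 1) / den2 : 0.0;
        out[j] = 3.0 * (a - b);
      }
    } else {
      double N2[2]; // degree-1 basis, indices i-1 .. i
      basis_funs(i, x, 1, N2);
      auto n2 = [&](int idx) -> double {
        int j = idx - (i - 1);
        return (j >= 0 && j <= 1) ? N2[j] : 0.0;
      };
      for (int j = 0; j < 4; ++j) {
        int bi = i - 3 + j;
        double den1 = knots[bi + 3] - knots[bi];
        double den2 = knots[bi + 4] - knots[bi + 1];
        double e0 = knots[bi + 2] - knots[bi];
        double e1 = knots[bi + 3] - knots[bi + 1];
        double e2 = knots[bi + 4] - knots[bi + 2];
        double t = 0.0;
        if (den1 > 0 && e0 > 0) t += n2(bi) / (den1 * e0);
        if (e1 > 0) {
          double v = n2(bi + 1);
          if (den1 > 0) t -= v / (den1 * e1);
          if (den2 > 0) t -= v / (den2 * e1);
        }
        if (den2 > 0 && e2 > 0) t += n2(bi + 2) / (den2 * e2);
        out[j] = 6.0 * t;
      }
    }
    return i - 3;
  }

  // exact curvature penalty matrix (3-pt Gauss per interval)
  arma::mat penalty() const {
    arma::mat Om(k, k, arma::fill::zeros);
    const double gx[3] = {-0.7745966692414834, 0.0, 0.7745966692414834};
    const double gw[3] = {5.0 / 9.0, 8.0 / 9.0, 5.0 / 9.0};
    int m = k - 3;
    for (int iv = 0; iv < m; ++iv) {
      double a = knots[3 + iv], b = knots[4 + iv];
      double h2 = (b - a) / 2.0, mid = (a + b) / 2.0;
      for (int g = 0; g < 3; ++g) {
        double x = mid + h2 * gx[g];
        double v[4];
        int f = basis(x, 2, v);
        double w = gw[g] * h2;
        for (int p = 0; p < 4; ++p)
          for (int q = 0; q < 4; ++q)
            Om(f + p, f + q) += w * v[p] * v[q];
      }
    }
    return Om;
  }
};

struct FitResult {
  arma::vec coef;
  double sse, edf, lambda, gcv;
  bool ok;
};

static FitResult fit_lambda(const arma::mat& BtB, const arma::vec& Bty,
                            double yty, int n, const arma::mat& Om,
                            double lambda) {
  FitResult r; r.ok = false; r.lambda = lambda;
  arma::mat A = BtB + lambda * Om;
  A.diag() += 1e-9 * (arma::trace(BtB) / BtB.n_rows + 1.0);
  arma::mat L;
  if (!arma::chol(L, A, "lower")) return r;
  arma::vec c = arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), Bty));
  // edf = tr( A^{-1} BtB )
  arma::mat X = arma::solve(arma::trimatu(L.t()),
                            arma::solve(arma::trimatl(L), BtB));
  double edf = arma::trace(X);
  double sse = yty - 2.0 * arma::dot(c, Bty) + arma::dot(c, BtB * c);
  if (sse < 0) sse = 0;
  double denom = (double)n - edf;
  double gcv = (denom > 1e-6) ? (double)n * sse / (denom * denom) : R_PosInf;
  r.coef = c; r.sse = sse; r.edf = edf; r.gcv = gcv; r.ok = true;
  return r;
}

static void accumulate(const CubicBasis& bs, const arma::vec& x,
                       const arma::vec& y, arma::mat& BtB, arma::vec& Bty,
                       double& yty) {
  double v[4];
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    int f = bs.basis(x[i], 0, v);
    double yi = y[i];
    yty += yi * yi;
    for (int p = 0; p < 4; ++p) {
      Bty[f + p] += v[p] * yi;
      for (int q = 0; q < 4; ++q) BtB(f + p, f + q) += v[p] * v[q];
    }
  }
}

// [[Rcpp::export(name = ".pspline_fit_cpp")]]
List pspline_fit_cpp(const arma::vec& x, const arma::vec& y, double xmax,
                     double dk, double lambda) {
  if (x.n_elem != y.n_elem) stop("x and y lengths differ");
  CubicBasis bs(xmax, dk);
  if ((int)x.n_elem < bs.k + 1)
    stop("too few points (%d) for %d basis functions", (int)x.n_elem, bs.k);
  arma::mat BtB(bs.k, bs.k, arma::fill::zeros);
  arma::vec Bty(bs.k, arma::fill::zeros);
  double yty = 0.0;
  accumulate(bs, x, y, BtB, Bty, yty);
  arma::mat Om = bs.penalty();
  FitResult best; best.ok = false;
  if (lambda > 0) {
    best = fit_lambda(BtB, Bty, yty, x.n_elem, Om, lambda);
  } else {
    // GCV over a log-spaced grid; lambda is in data units, so scale the grid
    // by the ratio of the cross-product and penalty magnitudes.
    double scale = (arma::trace(BtB) + 1.0) / (arma::trace(Om) + 1.0);
    for (int i = 0; i < 19; ++i) {
      double lg = -5.0 + 10.0 * i / 18.0;
      FitResult r = fit_lambda(BtB, Bty, yty, x.n_elem, Om,
                               scale * std::pow(10.0, lg));
      if (r.ok && (!best.ok || r.gcv < best.gcv)) best = r;
    }
  }
  if (!best.ok) stop("spline fit failed");
  return List::create(_["coef"] = best.coef, _["knots"] = bs.knots,
                      _["xmax"] = xmax, _["dk"] = dk, _["n"] = (int)x.n_elem,
                      _["sse"] = best.sse, _["edf"] = best.edf,
                      _["lambda"] = best.lambda, _["gcv"] = best.gcv);
}

// [[Rcpp::export(name = ".pspline_eval_cpp")]]
arma::vec pspline_eval_cpp(const arma::vec& coef, double xmax, double dk,
                           const arma::vec& x, int deriv) {
  CubicBasis bs(xmax, dk);
  if ((int)coef.n_elem != bs.k) stop("coefficient length mismatch");
  arma::vec out(x.n_elem);
  double v[4];
  for (arma::uword i = 0; i < x.n_elem; ++i) {
    int f = bs.basis(x[i], deriv, v);
    double s = 0;
    for (int p = 0; p < 4; ++p) s += v[p] * coef[f + p];
    out[i] = s;
  }
  return out;
}

// Mean squared residual of the radial-profile spline for a candidate bead
// center: the objective minimized during center optimization. Scatter =
// every tile pixel within rmax of (cx, cy); coordinates are 0-based
// (x = column, y = row).
// [[Rcpp::export(name = ".profile_mse_cpp")]]
double profile_mse_cpp(const arma::mat& tile, double cx, double cy,
                       double rmax, double dk, double lambda) {
  int nr = tile.n_rows, nc = tile.n_cols;
  CubicBasis bs(rmax, dk);
  arma::mat BtB(bs.k, bs.k, arma::fill::zeros);
  arma::vec Bty(bs.k, arma::fill::zeros);
  double yty = 0.0;
  int n = 0;
  double v[4];
  int j0 = std::max(0, (int)std::floor(cx - rmax)),
      j1 = std::min(nc - 1, (int)std::ceil(cx + rmax)),
      i0 = std::max(0, (int)std::floor(cy - rmax)),
      i1 = std::min(nr - 1, (int)std::ceil(cy + rmax));
  double r2max = rmax * rmax;
  for (int j = j0; j <= j1; ++j) {
    double dx = j - cx, dx2 = dx * dx;
    for (int i = i0; i <= i1; ++i) {
      double dy = i - cy;
      double r2 = dx2 + dy * dy;
      if (r2 > r2max) continue;
      double r = std::sqrt(r2);
      double yi = tile(i, j);
      int f = bs.basis(r, 0, v);
      yty += yi * yi;
      for (int p = 0; p < 4; ++p) {
        Bty[f + p] += v[p] * yi;
        for (int q = 0; q < 4; ++q) BtB(f + p, f + q) += v[p] * v[q];
      }
      ++n;
    }
  }
  if (n < bs.k + 1) return R_PosInf;
  arma::mat Om = bs.penalty();
  FitResult r = fit_lambda(BtB, Bty, yty, n, Om, lambda);
  if (!r.ok) return R_PosInf;
  return r.sse / (double)n;
}
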