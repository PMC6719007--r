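#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// xorshift32: deterministic, platform-independent permutation source so
// that fits are bit-reproducible without touching R's RNG.
static inline uint32_t xs32(uint32_t& s) {
  s ^= s << 13; s ^= s >> 17; s ^= s << 5; return s;
}

// Dual coordinate descent for L2-regularized epsilon-insensitive linear SVR
// in the beta = (alpha+ - alpha-) formulation:
//   min_beta 1/2 beta' Q beta + eps * sum|beta_i| - y' beta,  |beta_i| <= C,
// with Q = X X' and w = X' beta. The intercept is an augmented constant
// column supplied by the caller (targets are centred there, so the
// regularization on the bias coordinate is immaterial in practice).
// Coordinates are visited in a deterministically permuted order with
// LIBLINEAR-style shrinking of bound/inactive coordinates; stops when the
// largest projected-gradient violation over the full set falls below tol.
// Xt is the d x n transposed design (samples in columns, contiguous).
// [[Rcpp::export(name = ".svr_dcd")]]
List svr_dcd(const NumericMatrix& Xt, const NumericVector& y,
             double C, double eps, double tol, int max_sweeps) {
  const int d = Xt.nrow(), n = Xt.ncol();
  std::vector<double> beta(n, 0.0), w(d, 0.0), qii(n);
  const double* X = REAL(Xt);
  for (int i = 0; i < n; ++i) {
    const double* xi = X + (size_t)i * d;
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += xi[j] * xi[j];
    qii[i] = s;
  }
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int n_active = n;
  uint32_t rng = 2463534242u;
  double gmax_old = R_PosInf;
  bool converged = false;
  int sweeps_done = 0;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int i = n_active - 1; i > 0; --i) { // Fisher-Yates, deterministic
      const int j = (int)(xs32(rng) % (uint32_t)(i + 1));
      std::swap(active[i], active[j]);
    }
    double gmax = 0.0;
    for (int k = 0; k < n_active; ++k) {
      const int i = active[k];
      if (qii[i] <= 0.0) continue;
      const double* xi = X + (size_t)i * d;
      double xw = 0.0;
      for (int j = 0; j < d; ++j) xw += xi[j] * w[j];
      const double g = xw - y[i];
      const double gp = g + eps, gn = g - eps;
      const double b = beta[i];
      double viol = 0.0;
      bool shrink = false;
      if (b == 0.0) {
        if (gp < 0.0) viol = -gp;
        else if (gn > 0.0) viol = gn;
        else if (gp > gmax_old && gn < -gmax_old) shrink = true;
      } else if (b >= C) {
        if (gp > 0.0) viol = gp;
        else if (gp < -gmax_old) shrink = true;
      } else if (b <= -C) {
        if (gn < 0.0) viol = -gn;
        else if (gn > gmax_old) shrink = true;
      } else {
        viol = (b > 0.0) ? std::fabs(gp) : std::fabs(gn);
      }
      if (shrink) {
        --n_active;
        std::swap(active[k], active[n_active]);
        --k;
        continue;
      }
      if (viol > gmax) gmax = viol;
      // exact coordinate minimizer via soft threshold, clipped to the box
      const double u = qii[i] * b - g;
      double z = 0.0;
      if (u > eps)       z = (u - eps) / qii[i];
      else if (u < -eps) z = (u + eps) / qii[i];
      if (z > C) z = C; else if (z < -C) z = -C;
      const double delta = z - b;
      if (delta != 0.0) {
        for (int j = 0; j < d; ++j) w[j] += delta * xi[j];
        beta[i] = z;
      }
    }
    sweeps_done = sweep + 1;
    if (gmax < tol) {
      if (n_active == n) { converged = true; break; }
      n_active = n;              // unshrink and confirm on the full set
      gmax_old = R_PosInf;
    } else {
      gmax_old = gmax;
      if (gmax_old < tol) gmax_old = tol;
    }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["sweeps"] = sweeps_done,
                      _["converged"] = converged);
}
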