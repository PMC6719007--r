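#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Scan all ordered pairs (numerator i, denominator j) of candidate length
// intervals and return the pair whose per-sample sum ratio has maximal
// Pearson correlation with the (already centred) targets.
//
// St:    N x m matrix, column i = per-sample proportion sums of interval i
// tc:    centred targets (length N)
// width: interval widths in bp (length m), used for tie-breaking
// lo:    interval start lengths (length m), used for lexicographic ties
// Ties: higher correlation wins; then smaller width(i)+width(j); then
// lexicographic (lo[i], lo[j]).
// [[Rcpp::export(name = ".interval_pair_scan")]]
List interval_pair_scan(const NumericMatrix& St, const NumericVector& tc,
                        const IntegerVector& width, const IntegerVector& lo) {
  const int N = St.nrow(), m = St.ncol();
  double stt = 0.0;
  for (int k = 0; k < N; ++k) stt += tc[k] * tc[k];
  double bestcor = R_NegInf;
  int besti = -1, bestj = -1;
  std::vector<double> dinv(N), ratio(N);
  for (int j = 0; j < m; ++j) {
    const double* Sj = &St(0, j);
    bool ok = true;
    for (int k = 0; k < N; ++k) {
      if (Sj[k] <= 0.0) { ok = false; break; }
      dinv[k] = 1.0 / Sj[k];
    }
    if (!ok) continue;
    for (int i = 0; i < m; ++i) {
      if (i == j) continue;
      const double* Si = &St(0, i);
      double s = 0.0, ss = 0.0, cross = 0.0;
      for (int k = 0; k < N; ++k) {
        const double r = Si[k] * dinv[k];
        s += r; ss += r * r; cross += r * tc[k];
      }
      const double var = ss - s * s / N;
      if (!(var > 1e-300)) continue;
      const double cor = cross / std::sqrt(var * stt);
      if (!R_finite(cor)) continue;
      bool take = false;
      if (cor > bestcor) take = true;
      else if (cor == bestcor && besti >= 0) {
        const int wnew = width[i] + width[j], wold = width[besti] + width[bestj];
        if (wnew < wold) take = true;
        else if (wnew == wold) {
          if (lo[i] < lo[besti] ||
              (lo[i] == lo[besti] && lo[j] < lo[bestj])) take = true;
        }
      }
      if (take) { bestcor = cor; besti = i; bestj = j; }
    }
  }
  if (besti < 0)
    return List::create(_["i"] = NA_INTEGER, _["j"] = NA_INTEGER,
                        _["cor"] = NA_REAL);
  return List::create(_["i"] = besti + 1, _["j"] = bestj + 1,
                      _["cor"] = bestcor);
}
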