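// Heavy statistical kernels: mean squared displacement over all time
// origins, the individual auto-correlation of the direction of motion along
// each twitcher's path, and instantaneous pair correlations of direction /
// orientation binned by minimum-image separation.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// com: array (F, N, 2); lags in frame units
// [[Rcpp::export]]
List msd_cpp(NumericVector com, int F, int N, IntegerVector lags,
             int origin_stride) {
  const int L = lags.size();
  NumericVector m2(L), m4(L);
  NumericVector cnt(L);
  const double* cx = REAL(com);
  const double* cy = cx + (size_t)F * N;
  for (int l = 0; l < L; ++l) {
    const int lag = lags[l];
    double s2 = 0.0, s4 = 0.0;
    long n = 0;
    for (int g = 0; g < N; ++g) {
      const double* x = cx + (size_t)F * g;
      const double* y = cy + (size_t)F * g;
      for (int f = 0; f + lag < F; f += origin_stride) {
        const double dx = x[f + lag] - x[f], dy = y[f + lag] - y[f];
        const double r2 = dx * dx + dy * dy;
        s2 += r2; s4 += r2 * r2; ++n;
      }
    }
    m2[l] = n ? s2 / n : NA_REAL;
    m4[l] = n ? s4 / n : NA_REAL;
    cnt[l] = (double)n;
  }
  return List::create(_["msd"] = m2, _["m4"] = m4, _["n"] = cnt);
}

// Individual auto-correlation of direction of motion vs distance travelled.
// For each origin with a defined direction, record v(0).v(j) at the first
// sample j at which the abscissa (cumulative path length, or net
// displacement if path = false) reaches each bin edge.
// [[Rcpp::export]]
List iac_cpp(NumericVector com, NumericVector vel, int F, int N,
             double bin_width, int nbins, int origin_stride, bool path) {
  NumericVector val(nbins), cnt(nbins);
  const double* cx = REAL(com);
  const double* cy = cx + (size_t)F * N;
  const double* vx = REAL(vel);
  const double* vy = vx + (size_t)F * N;
  std::vector<double> s(F), ux(F), uy(F);
  std::vector<char> ok(F);
  for (int g = 0; g < N; ++g) {
    const double* x = cx + (size_t)F * g;
    const double* y = cy + (size_t)F * g;
    const double* wx = vx + (size_t)F * g;
    const double* wy = vy + (size_t)F * g;
    // cumulative path length and unit directions
    s[0] = 0.0;
    for (int f = 1; f < F; ++f) {
      const double dx = x[f] - x[f - 1], dy = y[f] - y[f - 1];
      s[f] = s[f - 1] + std::sqrt(dx * dx + dy * dy);
    }
    for (int f = 0; f < F; ++f) {
      const double sp = std::sqrt(wx[f] * wx[f] + wy[f] * wy[f]);
      if (R_finite(sp) && sp > 0.0) {
        ux[f] = wx[f] / sp; uy[f] = wy[f] / sp; ok[f] = 1;
      } else ok[f] = 0;
    }
    for (int f0 = 0; f0 < F; f0 += origin_stride) {
      if (!ok[f0]) continue;
      int b = 0;
      for (int j = f0 + 1; j < F && b < nbins; ++j) {
        double dr;
        if (path) dr = s[j] - s[f0];
        else {
          const double dx = x[j] - x[f0], dy = y[j] - y[f0];
          dr = std::sqrt(dx * dx + dy * dy);
        }
        while (b < nbins && dr >= (b + 1) * bin_width) {
          if (ok[j]) {
            val[b] += ux[f0] * ux[j] + uy[f0] * uy[j];
            cnt[b] += 1.0;
          }
          ++b;
        }
      }
    }
  }
  for (int b = 0; b < nbins; ++b)
    val[b] = cnt[b] > 0 ? val[b] / cnt[b] : NA_REAL;
  return List::create(_["value"] = val, _["n"] = cnt);
}

// Pair correlation of a per-twitcher unit vector field, binned by
// minimum-image com separation. mode: 0 = dot, 1 = cos 2theta (headless),
// 2 = 3*(dot - 2/3) on canonicalised directors.
// frames: 1-based frame indices to pool.
// [[Rcpp::export]]
List pac_cpp(NumericVector comw, NumericVector u, LogicalVector ok,
             int F, int N, int mode, double bin_width, int nbins,
             IntegerVector frames, double boxL) {
  NumericVector val(nbins), cnt(nbins);
  const double* cx = REAL(comw);
  const double* cy = cx + (size_t)F * N;
  const double* ux = REAL(u);
  const double* uy = ux + (size_t)F * N;
  const int* okp = LOGICAL(ok);
  const double halfL = 0.5 * boxL;
  for (int q = 0; q < frames.size(); ++q) {
    const int f = frames[q] - 1;
    for (int g = 0; g < N; ++g) {
      if (okp[f + (size_t)F * g] != 1) continue;
      const double xg = cx[f + (size_t)F * g], yg = cy[f + (size_t)F * g];
      const double ax = ux[f + (size_t)F * g], ay = uy[f + (size_t)F * g];
      for (int h = g + 1; h < N; ++h) {
        if (okp[f + (size_t)F * h] != 1) continue;
        double dx = cx[f + (size_t)F * h] - xg;
        double dy = cy[f + (size_t)F * h] - yg;
        if (dx > halfL) dx -= boxL; else if (dx < -halfL) dx += boxL;
        if (dy > halfL) dy -= boxL; else if (dy < -halfL) dy += boxL;
        const double r = std::sqrt(dx * dx + dy * dy);
        const int b = (int)(r / bin_width);
        if (b >= nbins) continue;
        const double d = ax * ux[f + (size_t)F * h] + ay * uy[f + (size_t)F * h];
        double v;
        if (mode == 1) v = 2.0 * d * d - 1.0;
        else if (mode == 2) v = 3.0 * (d - 2.0 / 3.0);
        else v = d;
        val[b] += v; cnt[b] += 1.0;
      }
    }
  }
  for (int b = 0; b < nbins; ++b)
    val[b] = cnt[b] > 0 ? val[b] / cnt[b] : NA_REAL;
  return List::create(_["value"] = val, _["n"] = cnt);
}
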