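#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// Per-scale least-squares polynomial detrender. The design matrix uses time
// rescaled to [-1, 1] for conditioning; the fitted subspace (polynomials of
// degree <= order) is what matters, not the basis.
struct Detrender {
  int n, p;
  bool valid;
  std::vector<double> X;      // n x p, column-major
  std::vector<double> XtXinv; // p x p

  Detrender(int n_, int order)
      : n(n_), p(order + 1), valid(n_ >= order + 2),
        X(static_cast<size_t>(n_) * (order + 1)),
        XtXinv(static_cast<size_t>(order + 1) * (order + 1), 0.0) {
    if (!valid) return;
    for (int t = 0; t < n; ++t) {
      double ts = (n == 1) ? 0.0 : (2.0 * t - (n - 1)) / (double)(n - 1);
      double v = 1.0;
      for (int j = 0; j < p; ++j) {
        X[t + (size_t)j * n] = v;
        v *= ts;
      }
    }
    // A = X'X, then invert in place (p is tiny: order + 1)
    std::vector<double> M(p * p);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) {
        double s = 0.0;
        for (int t = 0; t < n; ++t) s += X[t + (size_t)i * n] * X[t + (size_t)j * n];
        M[i + j * p] = s;
      }
    std::vector<double> I(p * p, 0.0);
    for (int i = 0; i < p; ++i) I[i + i * p] = 1.0;
    for (int c = 0; c < p; ++c) {
      int piv = c;
      for (int r = c + 1; r < p; ++r)
        if (std::fabs(M[r + c * p]) > std::fabs(M[piv + c * p])) piv = r;
      if (piv != c)
        for (int j = 0; j < p; ++j) {
          std::swap(M[c + j * p], M[piv + j * p]);
          std::swap(I[c + j * p], I[piv + j * p]);
        }
      double d = M[c + c * p];
      if (d == 0.0) { valid = false; return; }
      for (int j = 0; j < p; ++j) { M[c + j * p] /= d; I[c + j * p] /= d; }
      for (int r = 0; r < p; ++r) {
        if (r == c) continue;
        double f = M[r + c * p];
        if (f == 0.0) continue;
        for (int j = 0; j < p; ++j) {
          M[r + j * p] -= f * M[c + j * p];
          I[r + j * p] -= f * I[c + j * p];
        }
      }
    }
    XtXinv = I;
  }

  // residual sum of squares of the segment y[0..n)
  double rss(const double *y) const {
    double xty[8], beta[8]; // p <= 8 is far beyond any sane detrend order
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      const double *xc = &X[(size_t)j * n];
      for (int t = 0; t < n; ++t) s += xc[t] * y[t];
      xty[j] = s;
    }
    for (int i = 0; i < p; ++i) {
      double s = 0.0;
      for (int j = 0; j < p; ++j) s += XtXinv[i + j * p] * xty[j];
      beta[i] = s;
    }
    double ss = 0.0;
    for (int t = 0; t < n; ++t) {
      double fit = 0.0;
      for (int j = 0; j < p; ++j) fit += X[t + (size_t)j * n] * beta[j];
      double r = y[t] - fit;
      ss += r * r;
    }
    return ss;
  }
};

void fluct_from_profile(const double *y, int N, const IntegerVector &scales,
                        const std::vector<Detrender> &cache, double *Fout) {
  for (int si = 0; si < scales.size(); ++si) {
    int n = scales[si];
    int m = (n > 0) ? N / n : 0;
    if (m < 1 || !cache[si].valid) {
      Fout[si] = NA_REAL;
      continue;
    }
    double ss = 0.0;
    for (int s = 0; s < m; ++s) ss += cache[si].rss(y + (size_t)s * n);
    Fout[si] = std::sqrt(ss / (double)((size_t)m * n));
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector dfa_fluct_cpp(NumericVector profile, IntegerVector scales, int order) {
  int N = profile.size();
  std::vector<Detrender> cache;
  cache.reserve(scales.size());
  for (int si = 0; si < scales.size(); ++si) cache.emplace_back(scales[si], order);
  NumericVector F(scales.size());
  fluct_from_profile(REAL(profile), N, scales, cache, REAL(F));
  return F;
}

// alpha per window: profile of the mean-centred excerpt, fluctuation function,
// then OLS slope of log10 F on log10 n over the usable (finite, positive) scales.
// [[Rcpp::export]]
NumericVector sliding_alpha_cpp(NumericVector x, int window, int step,
                                IntegerVector scales, int order) {
  int N = x.size();
  if (window > N) stop("window longer than signal");
  int nw = (N - window) / step + 1;
  int ns = scales.size();
  std::vector<Detrender> cache;
  cache.reserve(ns);
  for (int si = 0; si < ns; ++si) cache.emplace_back(scales[si], order);
  std::vector<double> lg_n(ns);
  for (int si = 0; si < ns; ++si) lg_n[si] = std::log10((double)scales[si]);

  std::vector<double> prof(window), F(ns);
  NumericVector alphas(nw);
  const double *xs = REAL(x);
  for (int w = 0; w < nw; ++w) {
    const double *seg = xs + (size_t)w * step;
    double mean = 0.0;
    for (int t = 0; t < window; ++t) mean += seg[t];
    mean /= window;
    double acc = 0.0;
    for (int t = 0; t < window; ++t) {
      acc += seg[t] - mean;
      prof[t] = acc;
    }
    fluct_from_profile(prof.data(), window, scales, cache, F.data());
    // OLS of log10 F vs log10 n
    double sx = 0, sy = 0, sxx = 0, sxy = 0;
    int k = 0;
    for (int si = 0; si < ns; ++si) {
      if (!R_finite(F[si]) || F[si] <= 0.0) continue;
      double lx = lg_n[si], ly = std::log10(F[si]);
      sx += lx; sy += ly; sxx += lx * lx; sxy += lx * ly;
      ++k;
    }
    if (k < 3) {
      alphas[w] = NA_REAL;
    } else {
      double den = sxx - sx * sx / k;
      alphas[w] = (sxy - sx * sy / k) / den;
    }
  }
  return alphas;
}

// Direct-form II transposed IIR filter; caller guarantees a[0] == 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a, NumericVector x) {
  int nb = b.size(), na = a.size(), N = x.size();
  int nz = std::max(nb, na) - 1;
  std::vector<double> z(nz > 0 ? nz : 1, 0.0);
  NumericVector y(N);
  for (int i = 0; i < N; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + (nz > 0 ? z[0] : 0.0);
    for (int j = 1; j <= nz; ++j) {
      double bj = (j < nb) ? b[j] : 0.0;
      double aj = (j < na) ? a[j] : 0.0;
      double znext = (j < nz) ? z[j] : 0.0;
      z[j - 1] = bj * xi - aj * yi + znext;
    }
    y[i] = yi;
  }
  return y;
}
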