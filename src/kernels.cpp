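// Quadratic-cost kernels behind the attractor-based estimators.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static inline double sqdist_cols(const double* x, int M, int m, int i, int j) {
  double s = 0.0;
  for (int c = 0; c < m; ++c) {
    double d = x[i + c * M] - x[j + c * M];
    s += d * d;
  }
  return s;
}

// Correlation integral C(r) for every r in `rgrid` (ascending), counting
// ordered pairs |i - j| > theiler, normalized by the number of such pairs.
// [[Rcpp::export]]
NumericVector corr_integral(NumericMatrix X, NumericVector rgrid, int theiler) {
  const int M = X.nrow(), G = rgrid.size();
  const int mdim = X.ncol();
  const double* xp = REAL(X);
  std::vector<double> r2(G);
  for (int g = 0; g < G; ++g) r2[g] = rgrid[g] * rgrid[g];
  const double rmax2 = r2[G - 1];
  std::vector<double> counts(G, 0.0);
  double npairs = 0.0;
  for (int i = 0; i < M; ++i) {
    for (int j = i + theiler + 1; j < M; ++j) {
      double d2 = sqdist_cols(xp, M, mdim, i, j);
      npairs += 1.0;
      if (d2 > rmax2) continue;
      // first grid point with r^2 >= d2; all larger r count the pair
      int lo = 0, hi = G - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (r2[mid] >= d2) hi = mid; else lo = mid + 1;
      }
      counts[lo] += 1.0;
    }
  }
  NumericVector out(G);
  double acc = 0.0;
  for (int g = 0; g < G; ++g) {
    acc += counts[g];
    out[g] = npairs > 0 ? acc / npairs : NA_REAL;
  }
  return out;
}

// Deterministic subsample of pairwise distances (every `stride`-th pair)
// used to place the r grid.
// [[Rcpp::export]]
NumericVector pairwise_dist_sample(NumericMatrix X, int theiler, int maxpairs) {
  const int M = X.nrow();
  const int mdim = X.ncol();
  const double* xp = REAL(X);
  double total = 0.0;
  for (int i = 0; i < M; ++i) total += std::max(0, M - i - theiler - 1);
  int stride = std::max(1, (int)(total / std::max(1, maxpairs)));
  std::vector<double> out;
  out.reserve(maxpairs + 16);
  long k = 0;
  for (int i = 0; i < M; ++i)
    for (int j = i + theiler + 1; j < M; j += stride, k += stride)
      out.push_back(std::sqrt(sqdist_cols(xp, M, mdim, i, j)));
  return wrap(out);
}

// Rosenstein mean log-divergence curve: every `stride`-chosen reference
// state gets its nearest neighbour outside the Theiler window; the mean of
// log(distance after k steps) is taken over references valid for all
// k = 0..kmax.
// [[Rcpp::export]]
NumericVector rosenstein_curve(NumericMatrix X, int theiler, int kmax,
                               int maxref) {
  const int M = X.nrow(), m = X.ncol();
  const double* xp = REAL(X);
  const int last = M - 1 - kmax;  // references must be followable kmax steps
  if (last < 1) return NumericVector(0);
  const int stride = std::max(1, (last + 1) / std::max(1, maxref));
  std::vector<double> sums(kmax + 1, 0.0);
  int nref = 0;
  for (int i = 0; i <= last; i += stride) {
    double best = R_PosInf;
    int jbest = -1;
    for (int j = 0; j <= last; ++j) {
      if (std::abs(i - j) <= theiler) continue;
      double s = 0.0;
      for (int c = 0; c < m; ++c) {
        double d = xp[i + c * M] - xp[j + c * M];
        s += d * d;
        if (s >= best) break;
      }
      if (s < best && s > 0.0) { best = s; jbest = j; }
    }
    if (jbest < 0) continue;
    ++nref;
    for (int k = 0; k <= kmax; ++k) {
      double d2 = sqdist_cols(xp, M, m, i + k, jbest + k);
      sums[k] += 0.5 * std::log(std::max(d2, 1e-300));
    }
  }
  if (nref == 0) return NumericVector(0);
  NumericVector curve(kmax + 1);
  for (int k = 0; k <= kmax; ++k) curve[k] = sums[k] / nref;
  curve.attr("nref") = nref;
  return curve;
}

// Approximate-entropy log-mean term phi(m) = mean_i log(C_i^m(r)) with
// Chebyshev distance and self-matches included. Pairs are pruned through
// an index ordering on the first coordinate: only j with
// |x_j - x_i| <= r can match template i.
static double apen_phi(const double* x, int N, int m, double r,
                       const std::vector<int>& ord) {
  const int n = N - m + 1;
  if (n < 1) return NA_REAL;
  // counts via symmetric pair enumeration; self-match counts once
  std::vector<int> cnt(n, 1);
  const int No = ord.size();
  for (int a = 0; a < No; ++a) {
    int i = ord[a];
    if (i >= n) continue;
    for (int b = a + 1; b < No; ++b) {
      int j = ord[b];
      if (x[j] - x[i] > r && x[i] - x[j] > r) break;  // sorted: no more matches
      if (j >= n) continue;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (match) { ++cnt[i]; ++cnt[j]; }
    }
  }
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += std::log((double)cnt[i] / n);
  return acc / n;
}

// [[Rcpp::export]]
NumericVector apen_phis(NumericVector x, int m, double r) {
  const int N = x.size();
  const double* xp = REAL(x);
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return xp[a] < xp[b]; });
  return NumericVector::create(apen_phi(xp, N, m, r, ord),
                               apen_phi(xp, N, m + 1, r, ord));
}

// False-nearest-neighbour fractions for embedding dimensions 1..mmax.
// Distances between the <= maxref reference states and all states are
// grown one coordinate at a time, so the whole sweep costs
// O(maxref * M * mmax). A neighbour is false when appending the (m+1)-th
// coordinate stretches it by more than rtol, or beyond atol_sd. Stops
// early once a fraction falls below `target`.
// [[Rcpp::export]]
NumericVector fnn_fractions(NumericVector x, int tau, int mmax, double rtol,
                            double atol_sd, int theiler, int maxref,
                            double target) {
  const int N = x.size();
  const double* xp = REAL(x);
  NumericVector frac(mmax, NA_REAL);
  const int Mlast = N - mmax * tau;  // states extendable through all probes
  if (Mlast < 10) return frac;
  const int stride = std::max(1, Mlast / std::max(1, maxref));
  std::vector<int> refs;
  for (int i = 0; i < Mlast; i += stride) refs.push_back(i);
  const int R = refs.size();
  // partial squared distances between each reference and every state;
  // numerically coincident states (exact repeats of a periodic signal)
  // are not usable neighbours
  const double dup2 = std::pow(1e-7 * atol_sd, 2);
  std::vector<std::vector<double>> pd(R, std::vector<double>(Mlast, 0.0));
  for (int m = 1; m <= mmax; ++m) {
    const int off = (m - 1) * tau;
    int nflag = 0, ntot = 0;
    for (int a = 0; a < R; ++a) {
      const int i = refs[a];
      std::vector<double>& di = pd[a];
      const double xi = xp[i + off];
      double best = R_PosInf;
      int jbest = -1;
      for (int j = 0; j < Mlast; ++j) {
        const double d = xp[j + off] - xi;
        di[j] += d * d;
        if (std::abs(i - j) <= theiler) continue;
        if (di[j] < best && di[j] > dup2) { best = di[j]; jbest = j; }
      }
      if (jbest < 0) continue;
      const double dnew = std::fabs(xp[i + m * tau] - xp[jbest + m * tau]);
      const double dm = std::sqrt(best);
      ++ntot;
      if (dnew / dm > rtol || std::sqrt(best + dnew * dnew) > atol_sd)
        ++nflag;
    }
    frac[m - 1] = ntot > 0 ? (double)nflag / ntot : NA_REAL;
    if (ntot > 0 && frac[m - 1] < target) break;
  }
  return frac;
}
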