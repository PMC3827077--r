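#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Circular binary segmentation scan statistic.
//
// For a sequence x[0..n-1] the circular arc (i, j] (0 <= i < j <= n) is
// compared against its complement with a two-sample statistic that uses the
// pooled (whole-segment) standard deviation:
//   T(i,j) = |mean(arc) - mean(complement)| / (s * sqrt(1/n1 + 1/n2)).
// Both arc and complement must hold at least 2 points.
//
// To stay tractable on long sequences the maximisation is multiscale:
//   * all arcs of width <= wmax are scanned exactly;
//   * wider arcs are scanned on a coarse grid of step g = max(1, n/grid_target)
//     and the best grid hit is refined exhaustively within +-g of each end.
// The same statistic (same wmax/grid_target) is used for observed data and
// for the permutation / Monte-Carlo null, so the test stays calibrated.

struct ScanHit {
  int i;
  int j;
  double t;
};

static int g_min_width = 3;  // minimum points in arc and complement

static inline double arc_t(const std::vector<double>& S, int n, double s,
                           double total, int i, int j) {
  int n1 = j - i;
  int n2 = n - n1;
  if (n1 < g_min_width || n2 < g_min_width) return -1.0;
  double sum1 = S[j] - S[i];
  double d = sum1 / n1 - (total - sum1) / n2;
  double se = s * std::sqrt(1.0 / n1 + 1.0 / n2);
  if (se <= 0) return -1.0;
  return std::fabs(d) / se;
}

static ScanHit scan_max_t(const double* x, int n, int wmax, int grid_target) {
  ScanHit best = {0, 0, 0.0};
  if (n < 4) return best;
  std::vector<double> S(n + 1);
  S[0] = 0.0;
  for (int k = 0; k < n; ++k) S[k + 1] = S[k] + x[k];
  double total = S[n];
  double mean = total / n;
  double ss = 0.0;
  for (int k = 0; k < n; ++k) {
    double d = x[k] - mean;
    ss += d * d;
  }
  if (ss <= 0) return best;
  double s = std::sqrt(ss / (n - 1));

  // exact pass over short arcs
  int wlim = std::min(wmax, n - 2);
  for (int w = g_min_width; w <= wlim; ++w) {
    for (int i = 0; i + w <= n; ++i) {
      double t = arc_t(S, n, s, total, i, i + w);
      if (t > best.t) { best.i = i; best.j = i + w; best.t = t; }
    }
  }

  // coarse grid over wide arcs, then local refinement
  int g = std::max(1, n / std::max(1, grid_target));
  if (n - 2 > wlim) {
    for (int i = 0; i <= n - 2; i += g) {
      for (int j = i + wlim + 1; j <= n; j += g) {
        double t = arc_t(S, n, s, total, i, j);
        if (t > best.t) { best.i = i; best.j = j; best.t = t; }
      }
      double t = arc_t(S, n, s, total, i, n);  // boundary arcs the grid
      if (t > best.t) { best.i = i; best.j = n; best.t = t; }
    }
    for (int j = wlim + 1; j <= n; j += g) {   // may step over
      double t = arc_t(S, n, s, total, 0, j);
      if (t > best.t) { best.i = 0; best.j = j; best.t = t; }
    }
    int ilo = std::max(0, best.i - g), ihi = std::min(n - 2, best.i + g);
    int jlo = std::max(g_min_width, best.j - g), jhi = std::min(n, best.j + g);
    for (int i = ilo; i <= ihi; ++i) {
      for (int j = std::max(jlo, i + g_min_width); j <= jhi; ++j) {
        double t = arc_t(S, n, s, total, i, j);
        if (t > best.t) { best.i = i; best.j = j; best.t = t; }
      }
    }
  }
  return best;
}

// [[Rcpp::export]]
List cpp_max_t(NumericVector x, int wmax, int grid_target, int min_width) {
  g_min_width = min_width;
  ScanHit h = scan_max_t(x.begin(), x.size(), wmax, grid_target);
  return List::create(_["i"] = h.i, _["j"] = h.j, _["t"] = h.t);
}

// Permutation p-value for the observed max-T, with early stopping: once the
// exceedance count guarantees p >= alpha the loop aborts.
// [[Rcpp::export]]
double cpp_perm_pval(NumericVector x, double obs, int nperm, double alpha,
                     int wmax, int grid_target, int seed, int min_width) {
  g_min_width = min_width;
  int n = x.size();
  std::vector<double> z(x.begin(), x.end());
  std::mt19937 rng(static_cast<unsigned>(seed));
  int cutoff = static_cast<int>(std::ceil(alpha * (nperm + 1)));
  int exceed = 0, done = 0;
  for (int b = 0; b < nperm; ++b) {
    for (int k = n - 1; k > 0; --k) {
      std::uniform_int_distribution<int> u(0, k);
      std::swap(z[k], z[u(rng)]);
    }
    ScanHit h = scan_max_t(z.data(), n, wmax, grid_target);
    if (h.t >= obs) ++exceed;
    ++done;
    if (exceed >= cutoff) return static_cast<double>(exceed + 1) / (done + 1);
    // no exceedance deep into the run: p-value is already far below alpha
    if (exceed == 0 && done >= 300 && done * alpha >= 3.0)
      return 1.0 / (done + 1);
  }
  return static_cast<double>(exceed + 1) / (nperm + 1);
}

// Monte-Carlo null quantile of the scan statistic on i.i.d. standard normal
// sequences of length n (used in place of permutations for long sequences;
// the statistic is studentized so the normal null is a good stand-in).
// [[Rcpp::export]]
NumericVector cpp_null_max_t(int n, int nrep, int wmax, int grid_target,
                             int seed, int min_width) {
  g_min_width = min_width;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::normal_distribution<double> nd(0.0, 1.0);
  std::vector<double> z(n);
  NumericVector out(nrep);
  for (int b = 0; b < nrep; ++b) {
    for (int k = 0; k < n; ++k) z[k] = nd(rng);
    out[b] = scan_max_t(z.data(), n, wmax, grid_target).t;
  }
  return out;
}

// Summed log standard-normal density of the Geary-Hinkley transform
//   z_i(r) = (r * rd_n_i - rd_t_i) / sqrt(r^2 * rd_n_i + rd_t_i)
// over a grid of candidate ratios (additive constants dropped).
// [[Rcpp::export]]
NumericVector cpp_gh_loglik(NumericVector rd_t, NumericVector rd_n,
                            NumericVector rgrid) {
  int n = rd_t.size(), m = rgrid.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    double r = rgrid[k], ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double denom = r * r * rd_n[i] + rd_t[i];
      if (denom <= 0) continue;
      double z = (r * rd_n[i] - rd_t[i]) / std::sqrt(denom);
      ll += -0.5 * z * z;
    }
    out[k] = ll;
  }
  return out;
}
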