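#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Template-pair counts for sample entropy, Chebyshev distance, self-matches
// excluded. Returns counts B (length m) and A (length m+1) over all
// unordered pairs i < j of template start indices 0..n-m-1, so both counts
// are taken over the same pair universe (Richman-Moorman convention).
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;           // templates of length m+1 start at 0..nt-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
        if (d >= r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      double dm = std::fabs(x[i + m] - x[j + m]);
      if (dm < r) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}

// Correlation-sum pair counts on delay-embedded points (Chebyshev distance
// for dim > 1, absolute difference for scalars). For each threshold t in
// the increasing grid, counts unordered pairs with distance <= t, one
// O(n^2) pass binning distances into the grid.
// [[Rcpp::export]]
NumericVector corr_sum_counts_cpp(NumericVector x, int dim, int delay,
                                  NumericVector tgrid) {
  const int n = x.size();
  const int np = n - (dim - 1) * delay;
  const int nt = tgrid.size();
  std::vector<double> bin(nt + 1, 0.0);  // bin[k]: first t index >= d is k
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d = 0.0;
      for (int k = 0; k < dim; ++k) {
        double dk = std::fabs(x[i + k * delay] - x[j + k * delay]);
        if (dk > d) d = dk;
      }
      // first index with tgrid[idx] >= d (binary search, grid is small)
      int lo = 0, hi = nt;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (tgrid[mid] >= d) hi = mid; else lo = mid + 1;
      }
      bin[lo] += 1.0;
    }
  }
  NumericVector counts(nt);
  double acc = 0.0;
  for (int k = 0; k < nt; ++k) {
    acc += bin[k];
    counts[k] = acc;               // pairs with d <= tgrid[k]
  }
  return counts;
}

// Quantiles of the pairwise-distance distribution on embedded points,
// approximated from an equal-width histogram over [0, max distance] built
// in one O(n^2) pass (exact enough to place a scaling region).
// [[Rcpp::export]]
NumericVector pair_dist_quantiles_cpp(NumericVector x, int dim, int delay,
                                      NumericVector probs, int nbins) {
  const int n = x.size();
  const int np = n - (dim - 1) * delay;
  double dmax = 0.0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d = 0.0;
      for (int k = 0; k < dim; ++k) {
        double dk = std::fabs(x[i + k * delay] - x[j + k * delay]);
        if (dk > d) d = dk;
      }
      if (d > dmax) dmax = d;
    }
  }
  if (dmax <= 0.0) return NumericVector(probs.size(), 0.0);
  std::vector<double> hist(nbins, 0.0);
  double total = 0.0;
  for (int i = 0; i < np - 1; ++i) {
    for (int j = i + 1; j < np; ++j) {
      double d = 0.0;
      for (int k = 0; k < dim; ++k) {
        double dk = std::fabs(x[i + k * delay] - x[j + k * delay]);
        if (dk > d) d = dk;
      }
      int b = (int)(d / dmax * (nbins - 1));
      hist[b] += 1.0;
      total += 1.0;
    }
  }
  NumericVector out(probs.size());
  for (int q = 0; q < probs.size(); ++q) {
    double target = probs[q] * total, acc = 0.0;
    int b = 0;
    while (b < nbins - 1 && acc + hist[b] < target) { acc += hist[b]; ++b; }
    out[q] = (b + 1.0) / nbins * dmax;
  }
  return out;
}

// Exact pair count for scalar series: number of unordered pairs with
// |x_i - x_j| <= t, for each t, via a two-pointer sweep over the sorted
// values. Equivalent to the O(n^2) double loop.
// [[Rcpp::export]]
NumericVector corr_count_sorted_cpp(NumericVector xs, NumericVector tgrid) {
  const int n = xs.size();
  const int nt = tgrid.size();
  NumericVector out(nt);
  for (int q = 0; q < nt; ++q) {
    const double t = tgrid[q];
    double cnt = 0.0;
    int j = 0;
    for (int i = 0; i < n; ++i) {
      if (j < i + 1) j = i + 1;
      while (j < n && xs[j] - xs[i] <= t) ++j;
      cnt += (j - 1) - i;        // pairs (i, i+1..j-1)
    }
    out[q] = cnt;
  }
  return out;
}

// Rosenstein-style divergence curve for the largest Lyapunov exponent:
// delay-embed, find each point's nearest neighbour outside a temporal
// exclusion window, then average log distances between the paired
// trajectories k steps ahead. Returns mean log divergence for k = 0..kmax
// (NaN where no pair contributes).
// [[Rcpp::export]]
NumericVector lyap_divergence_cpp(NumericVector x, int dim, int delay,
                                  int exclude, int kmax, int stride) {
  const int n = x.size();
  const int np = n - (dim - 1) * delay;
  std::vector<int> nn(np, -1);
  for (int i = 0; i < np; i += stride) {
    double best = std::numeric_limits<double>::infinity();
    int bestj = -1;
    for (int j = 0; j < np; ++j) {
      if (std::abs(i - j) <= exclude) continue;
      double d2 = 0.0;
      for (int k = 0; k < dim; ++k) {
        double dk = x[i + k * delay] - x[j + k * delay];
        d2 += dk * dk;
        if (d2 >= best) break;
      }
      if (d2 < best) { best = d2; bestj = j; }
    }
    nn[i] = bestj;
  }
  NumericVector out(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    double s = 0.0;
    int cnt = 0;
    for (int i = 0; i < np; i += stride) {
      int j = nn[i];
      if (j < 0 || i + k >= np || j + k >= np) continue;
      double d2 = 0.0;
      for (int q = 0; q < dim; ++q) {
        double dq = x[i + k + q * delay] - x[j + k + q * delay];
        d2 += dq * dq;
      }
      double d = std::sqrt(d2);
      if (d > 0.0) { s += std::log(d); ++cnt; }
    }
    out[k] = cnt > 0 ? s / cnt : NA_REAL;
  }
  return out;
}
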