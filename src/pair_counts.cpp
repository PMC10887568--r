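#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise template matching kernels. Each kernel first gathers the
// template entries into a compact per-anchor buffer (the image accesses
// are scattered; the pair loop then runs over contiguous memory), and
// counts unordered pairs whose Chebyshev distance is at most r.
//
// Buffer layout per anchor, length (m+1)^2: the m x m block first
// (entries 0..m*m-1, column-major within the block), then the extension
// entries of the (m+1)-template (last column, then last row). A pair
// matches at size m+1 iff it matches on all (m+1)^2 entries, and the
// extension can only be checked when the m-block already matches.

static void gather_templates(const NumericMatrix &u, const int *k0,
                             const int *l0, int n, int m, bool extended,
                             std::vector<double> &buf) {
  int len = extended ? (m + 1) * (m + 1) : m * m;
  buf.resize((size_t)n * len);
  for (int i = 0; i < n; ++i) {
    double *t = &buf[(size_t)i * len];
    int pos = 0;
    for (int dc = 0; dc < m; ++dc)
      for (int dr = 0; dr < m; ++dr)
        t[pos++] = u(k0[i] + dr, l0[i] + dc);
    if (extended) {
      for (int dr = 0; dr <= m; ++dr) t[pos++] = u(k0[i] + dr, l0[i] + m);
      for (int dc = 0; dc < m; ++dc) t[pos++] = u(k0[i] + m, l0[i] + dc);
    }
  }
}

static inline bool within_r(const double *x, const double *y, int len,
                            double r) {
  for (int s = 0; s < len; ++s) {
    double diff = x[s] - y[s];
    if (diff < 0.0) diff = -diff;
    if (diff > r) return false;
  }
  return true;
}

// Unordered matching pairs among the supplied anchors at template size m.
// Pairs of identical coordinates (duplicates from sampling with
// replacement) are skipped: a template never matches against itself.
// Counts returned as double: they can exceed the 32-bit integer range.
// [[Rcpp::export]]
double count_pairs_cpp(NumericMatrix u, IntegerVector k0, IntegerVector l0,
                       int m, double r) {
  int n = k0.size();
  if (n < 2) return 0.0;
  std::vector<double> buf;
  gather_templates(u, &k0[0], &l0[0], n, m, false, buf);
  int len = m * m;
  double count = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double *ti = &buf[(size_t)i * len];
    for (int j = i + 1; j < n; ++j) {
      if (k0[i] == k0[j] && l0[i] == l0[j]) continue;
      if (within_r(ti, &buf[(size_t)j * len], len, r)) count += 1.0;
    }
  }
  return count;
}

// One Monte Carlo epoch: matching pairs at sizes m and m+1 on the same
// anchors, in a single pass (an (m+1)-match requires the m-match first).
// [[Rcpp::export]]
NumericVector epoch_pair_counts_cpp(NumericMatrix u, IntegerVector k0,
                                    IntegerVector l0, int m, double r) {
  int n = k0.size();
  if (n < 2) return NumericVector::create(0.0, 0.0);
  std::vector<double> buf;
  gather_templates(u, &k0[0], &l0[0], n, m, true, buf);
  int core = m * m, len = (m + 1) * (m + 1);
  double A = 0.0, B = 0.0;
  for (int i = 0; i < n - 1; ++i) {
    const double *ti = &buf[(size_t)i * len];
    for (int j = i + 1; j < n; ++j) {
      if (k0[i] == k0[j] && l0[i] == l0[j]) continue;
      const double *tj = &buf[(size_t)j * len];
      if (!within_r(ti, tj, core, r)) continue;
      A += 1.0;
      if (within_r(ti + core, tj + core, len - core, r)) B += 1.0;
    }
  }
  return NumericVector::create(A, B);
}

// Matching pairs at template size s over the full restricted anchor grid
// k in [0, h - margin), l in [0, w - margin). The margin is m for the
// shared anchor set of a SampEn2D computation with base size m.
// [[Rcpp::export]]
double count_pairs_margin_cpp(NumericMatrix u, int s, double r, int margin) {
  int nk = u.nrow() - margin, nl = u.ncol() - margin;
  if (nk < 1 || nl < 1) return 0.0;
  long n = (long)nk * (long)nl;
  std::vector<int> k0(n), l0(n);
  for (long p = 0; p < n; ++p) {
    k0[p] = (int)(p % nk);
    l0[p] = (int)(p / nk);
  }
  std::vector<double> buf;
  gather_templates(u, k0.data(), l0.data(), (int)n, s, false, buf);
  int len = s * s;
  double count = 0.0;
  for (long i = 0; i < n - 1; ++i) {
    const double *ti = &buf[(size_t)i * len];
    for (long j = i + 1; j < n; ++j)
      if (within_r(ti, &buf[(size_t)j * len], len, r)) count += 1.0;
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return count;
}

// Exact SampEn2D numerator/denominator: matching pairs at sizes m and m+1
// over the shared restricted anchor grid (margin m), fused in one pass.
// [[Rcpp::export]]
NumericVector exact_pair_counts_cpp(NumericMatrix u, int m, double r) {
  int nk = u.nrow() - m, nl = u.ncol() - m;
  if (nk < 1 || nl < 1) return NumericVector::create(0.0, 0.0);
  long n = (long)nk * (long)nl;
  std::vector<int> k0(n), l0(n);
  for (long p = 0; p < n; ++p) {
    k0[p] = (int)(p % nk);
    l0[p] = (int)(p / nk);
  }
  std::vector<double> buf;
  gather_templates(u, k0.data(), l0.data(), (int)n, m, true, buf);
  int core = m * m, len = (m + 1) * (m + 1);
  double A = 0.0, B = 0.0;
  for (long i = 0; i < n - 1; ++i) {
    const double *ti = &buf[(size_t)i * len];
    for (long j = i + 1; j < n; ++j) {
      const double *tj = &buf[(size_t)j * len];
      if (!within_r(ti, tj, core, r)) continue;
      A += 1.0;
      if (within_r(ti + core, tj + core, len - core, r)) B += 1.0;
    }
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return NumericVector::create(A, B);
}
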