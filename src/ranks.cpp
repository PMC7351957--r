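#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>

using namespace Rcpp;

// Column-wise average ranks, centred and scaled to unit sum of squares so
// that crossprod() of two such matrices is the Spearman correlation matrix
// of the original columns. Constant columns (zero rank variance) are
// returned as all-NaN so the caller can flag the undefined correlation.
// [[Rcpp::export]]
NumericMatrix col_ranks_scaled(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  std::vector<std::pair<double, int> > v(n);
  const double mid = (n + 1) / 2.0;  // mean rank, ties or not
  for (int j = 0; j < m; ++j) {
    const double *col = &x(0, j);
    double *o = &out(0, j);
    for (int i = 0; i < n; ++i) {
      if (ISNAN(col[i])) stop("NA/NaN in column %d; ranks undefined", j + 1);
      v[i] = std::make_pair(col[i], i);
    }
    std::sort(v.begin(), v.end());
    int i = 0;
    double ss = 0.0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && v[k + 1].first == v[i].first) ++k;
      const double r = 0.5 * (i + k) + 1.0 - mid;  // centred average rank
      for (int t = i; t <= k; ++t) o[v[t].second] = r;
      ss += (k - i + 1) * r * r;
      i = k + 1;
    }
    if (ss <= 0.0) {
      for (int t = 0; t < n; ++t) o[t] = R_NaN;
    } else {
      const double inv = 1.0 / std::sqrt(ss);
      for (int t = 0; t < n; ++t) o[t] *= inv;
    }
  }
  return out;
}

// Element-wise mean of selected column pairs: out[, c] = (L[, iL[c]] +
// R[, iR[c]]) / 2, the progressive profile-averaging step done in one pass.
// [[Rcpp::export]]
NumericMatrix cross_mean(NumericMatrix L, NumericMatrix R,
                         IntegerVector iL, IntegerVector iR) {
  const int n = L.nrow(), m = iL.size();
  if (R.nrow() != n || iR.size() != m) stop("dimension mismatch");
  NumericMatrix out(n, m);
  for (int c = 0; c < m; ++c) {
    const double *l = &L(0, iL[c] - 1);
    const double *r = &R(0, iR[c] - 1);
    double *o = &out(0, c);
    for (int i = 0; i < n; ++i) o[i] = 0.5 * (l[i] + r[i]);
  }
  return out;
}

// Column-wise average ranks (ties.method = "average"), the rank convention
// required for Spearman correlation computed as Pearson on ranks.
// NA/NaN are not expected in expression profiles and are rejected.
// [[Rcpp::export]]
NumericMatrix col_ranks_avg(NumericMatrix x) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix out(n, m);
  out.attr("dimnames") = x.attr("dimnames");
  std::vector<int> idx(n);
  for (int j = 0; j < m; ++j) {
    const double *col = &x(0, j);
    for (int i = 0; i < n; ++i) {
      if (ISNAN(col[i])) stop("NA/NaN in column %d; ranks undefined", j + 1);
    }
    std::iota(idx.begin(), idx.end(), 0);
    std::sort(idx.begin(), idx.end(),
              [col](int a, int b) { return col[a] < col[b]; });
    int i = 0;
    while (i < n) {
      int k = i;
      while (k + 1 < n && col[idx[k + 1]] == col[idx[i]]) ++k;
      const double r = 0.5 * (i + k) + 1.0;  // average rank, 1-based
      for (int t = i; t <= k; ++t) out(idx[t], j) = r;
      i = k + 1;
    }
  }
  return out;
}
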