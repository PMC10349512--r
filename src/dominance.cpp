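#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// For each point i, count #{j : x_j <= x_i && y_j <= y_i}, inclusive in both
// coordinates and self-inclusive (so the result is always >= 1).  This is the
// denominator of the empirical cFDR estimator; a Fenwick tree over the
// rank-compressed y values gives O(n log n) instead of the O(n^2) double loop.
// Ties in x are handled by inserting a whole tie group before querying any of
// its members, which is what the inclusive <= comparison requires.
// [[Rcpp::export]]
IntegerVector dominance_count(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  IntegerVector out(n);
  if (n == 0) return out;

  std::vector<double> uy(y.begin(), y.end());
  std::sort(uy.begin(), uy.end());
  uy.erase(std::unique(uy.begin(), uy.end()), uy.end());
  const int m = (int)uy.size();

  std::vector<int> ry(n);
  for (int i = 0; i < n; ++i)
    ry[i] = (int)(std::lower_bound(uy.begin(), uy.end(), y[i]) - uy.begin()) + 1;

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return x[a] < x[b]; });

  std::vector<int> bit(m + 1, 0);
  auto add = [&](int i) { for (; i <= m; i += i & -i) ++bit[i]; };
  auto query = [&](int i) { int s = 0; for (; i > 0; i -= i & -i) s += bit[i]; return s; };

  int k = 0;
  while (k < n) {
    int k2 = k;
    const double xv = x[ord[k]];
    while (k2 < n && x[ord[k2]] == xv) ++k2;
    for (int t = k; t < k2; ++t) add(ry[ord[t]]);
    for (int t = k; t < k2; ++t) out[ord[t]] = query(ry[ord[t]]);
    k = k2;
  }
  return out;
}
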