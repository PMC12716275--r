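#include <Rcpp.h>
using namespace Rcpp;

// Open-ended DTW dynamic program over a precomputed local-cost matrix.
// Rows index the shorter sequence; the path starts at (0,0), uses steps
// {(1,0),(0,1),(1,1)}, and terminates at the minimum accumulated cost over
// the last row (both last row and last column when open_both is set, used
// for equal-length pairs so the dissimilarity is symmetric in its
// arguments). Ties prefer the diagonal step, then the row step.

// [[Rcpp::export]]
List oe_dtw_core(NumericMatrix cost, bool open_both) {
  const int n = cost.nrow(), m = cost.ncol();
  NumericMatrix acc(n, m);
  IntegerMatrix ptr(n, m); // 0 start, 1 diag, 2 from (i-1,j), 3 from (i,j-1)

  acc(0, 0) = cost(0, 0);
  ptr(0, 0) = 0;
  for (int i = 1; i < n; ++i) {
    acc(i, 0) = acc(i - 1, 0) + cost(i, 0);
    ptr(i, 0) = 2;
  }
  for (int j = 1; j < m; ++j) {
    acc(0, j) = acc(0, j - 1) + cost(0, j);
    ptr(0, j) = 3;
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 1; j < m; ++j) {
      double d = acc(i - 1, j - 1), u = acc(i - 1, j), l = acc(i, j - 1);
      double best = d;
      int p = 1;
      if (u < best) { best = u; p = 2; }
      if (l < best) { best = l; p = 3; }
      acc(i, j) = best + cost(i, j);
      ptr(i, j) = p;
    }
  }

  // open-ended termination
  int ei = n - 1, ej = 0;
  double best = acc(n - 1, 0);
  for (int j = 1; j < m; ++j)
    if (acc(n - 1, j) < best) { best = acc(n - 1, j); ej = j; }
  if (open_both) {
    for (int i = 0; i < n; ++i)
      if (acc(i, m - 1) < best) { best = acc(i, m - 1); ei = i; ej = m - 1; }
  }

  // backtrack
  std::vector<int> pi, pj;
  int i = ei, j = ej;
  while (true) {
    pi.push_back(i + 1);
    pj.push_back(j + 1);
    int p = ptr(i, j);
    if (p == 0) break;
    if (p == 1) { --i; --j; }
    else if (p == 2) { --i; }
    else { --j; }
  }
  const int len = (int)pi.size();
  IntegerMatrix path(len, 2);
  for (int k = 0; k < len; ++k) {
    path(k, 0) = pi[len - 1 - k];
    path(k, 1) = pj[len - 1 - k];
  }
  return List::create(_["total"] = best, _["path"] = path,
                      _["end_row"] = ei + 1, _["end_col"] = ej + 1);
}
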