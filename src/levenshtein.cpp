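#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

// Banded Levenshtein distance with cap: returns the exact distance when it
// is <= cap, otherwise cap + 1. The DP is restricted to a diagonal band of
// half-width cap, which is sufficient because any cell outside the band
// already implies distance > cap.
static int lev_capped(const std::string &a, const std::string &b, int cap) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (std::abs(la - lb) > cap) return cap + 1;
  if (la == 0) return lb;
  if (lb == 0) return la;
  const int inf = cap + 1;
  std::vector<int> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = (j <= cap) ? j : inf;
  for (int i = 1; i <= la; ++i) {
    int lo = std::max(1, i - cap);
    int hi = std::min(lb, i + cap);
    cur[0] = (i <= cap) ? i : inf;
    if (lo > 1) cur[lo - 1] = inf;
    int row_min = cur[0];
    for (int j = lo; j <= hi; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int del = (j <= i + cap - 1) ? prev[j] + 1 : inf;
      int ins = (j - 1 >= lo - 1) ? cur[j - 1] + 1 : inf;
      int v = std::min(sub, std::min(del, ins));
      cur[j] = std::min(v, inf);
      row_min = std::min(row_min, cur[j]);
    }
    if (hi < lb) cur[hi + 1 > lb ? lb : hi + 1] = inf;
    if (row_min > cap) return cap + 1;
    std::swap(prev, cur);
  }
  return std::min(prev[lb], inf);
}

// [[Rcpp::export]]
Rcpp::IntegerVector edit_distance_cpp(std::string a,
                                      std::vector<std::string> b,
                                      int cap) {
  Rcpp::IntegerVector out(b.size());
  for (size_t i = 0; i < b.size(); ++i) {
    out[i] = lev_capped(a, b[i], cap);
  }
  return out;
}
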