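#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Fast non-dominated sorting (maximization): returns the 0-based front index
// of every row. Deb's dominance-count algorithm, O(n^2 M).
//
// [[Rcpp::export]]
IntegerVector nds_rank(NumericMatrix P) {
  const int n = P.nrow(), M = P.ncol();
  IntegerVector rank(n, -1);
  if (n == 0) return rank;
  std::vector<std::vector<int>> dominates(n);
  std::vector<int> ndom(n, 0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool ge = true, gt = false, le = true, lt = false;
      for (int m = 0; m < M; ++m) {
        const double a = P(i, m), b = P(j, m);
        if (a < b) { ge = false; lt = true; }
        else if (a > b) { le = false; gt = true; }
        if (!ge && !le) break;
      }
      if (ge && gt) { dominates[i].push_back(j); ++ndom[j]; }
      else if (le && lt) { dominates[j].push_back(i); ++ndom[i]; }
    }
  }
  std::vector<int> current;
  for (int i = 0; i < n; ++i)
    if (ndom[i] == 0) current.push_back(i);
  int level = 0;
  while (!current.empty()) {
    std::vector<int> next;
    for (int i : current) {
      rank[i] = level;
      for (int j : dominates[i])
        if (--ndom[j] == 0) next.push_back(j);
    }
    current.swap(next);
    ++level;
  }
  return rank;
}
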