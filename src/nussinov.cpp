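#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// Base-pair maximisation over an explicit allowed-pair mask.
// dp[i][j] = max number of non-crossing pairs within [i, j] (0-based, inclusive)
// subject to j - i >= min_sep for every chosen pair (i, j).
// Traceback is deterministic: prefer pairing the left end, then the smallest
// partner index, so the same input always yields the same structure.

// [[Rcpp::export]]
IntegerMatrix nussinov_pairs_cpp(const LogicalMatrix& allowed, int min_sep) {
  const int L = allowed.nrow();
  if (allowed.ncol() != L) stop("allowed-pair mask must be square");
  if (L == 0) return IntegerMatrix(0, 2);

  std::vector<std::vector<int> > dp(L, std::vector<int>(L, 0));
  for (int span = min_sep; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      const int j = i + span;
      int best = dp[i + 1][j];  // i unpaired
      for (int k = i + min_sep; k <= j; ++k) {
        if (!allowed(i, k)) continue;
        int cand = 1;
        if (k - 1 >= i + 1) cand += dp[i + 1][k - 1];
        if (k + 1 <= j) cand += dp[k + 1][j];
        if (cand > best) best = cand;
      }
      dp[i][j] = best;
    }
  }

  std::vector<std::pair<int, int> > out;
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    const int i = stack.back().first;
    const int j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i < min_sep) continue;
    const int target = dp[i][j];
    if (target == 0) continue;
    bool paired = false;
    for (int k = i + min_sep; k <= j; ++k) {
      if (!allowed(i, k)) continue;
      int cand = 1;
      if (k - 1 >= i + 1) cand += dp[i + 1][k - 1];
      if (k + 1 <= j) cand += dp[k + 1][j];
      if (cand == target) {
        out.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }

  IntegerMatrix res(out.size(), 2);
  for (size_t r = 0; r < out.size(); ++r) {
    res(r, 0) = out[r].first;
    res(r, 1) = out[r].second;
  }
  return res;
}
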