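#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Canonical plus wobble pairing; N pairs with nothing.
static inline bool can_pair(char x, char y, bool allow_gu) {
  if ((x == 'A' && y == 'T') || (x == 'T' && y == 'A')) return true;
  if ((x == 'G' && y == 'C') || (x == 'C' && y == 'G')) return true;
  if (allow_gu && ((x == 'G' && y == 'T') || (x == 'T' && y == 'G'))) return true;
  return false;
}

// Nussinov maximum base pairing with a minimum hairpin loop of `min_loop`
// unpaired bases. Returns a 1-based partner vector (0 = unpaired).
// Traceback is deterministic: at (i, j), position i is paired whenever a
// pairing choice attains the optimum, and then with the outermost (largest k)
// optimal partner.
// [[Rcpp::export]]
IntegerVector nussinov_cpp(std::string s, int min_loop, bool allow_gu) {
  const int n = s.size();
  IntegerVector partner(n, 0);
  if (n < min_loop + 2) return partner;
  std::vector< std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k], allow_gu)) continue;
        int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
        int right = (k < j) ? M[k + 1][j] : 0;
        int v = inner + right + 1;
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  // iterative traceback over (i, j) intervals
  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < min_loop + 1) continue;
    int cur = M[i][j];
    int chosen = -1;
    for (int k = j; k >= i + min_loop + 1; --k) {  // outermost partner first
      if (!can_pair(s[i], s[k], allow_gu)) continue;
      int inner = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
      int right = (k < j) ? M[k + 1][j] : 0;
      if (inner + right + 1 == cur) { chosen = k; break; }
    }
    if (chosen >= 0) {
      partner[i] = chosen + 1;
      partner[chosen] = i + 1;
      if (chosen - i - 1 > min_loop) stack.push_back(std::make_pair(i + 1, chosen - 1));
      if (chosen < j) stack.push_back(std::make_pair(chosen + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  return partner;
}
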