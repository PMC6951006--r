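#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <vector>
using namespace Rcpp;

// Match only when both bases are equal and neither is N: ambiguity never
// counts as identity.
static inline double subscore(char x, char y, double match, double mismatch) {
  return (x == y && x != 'N') ? match : mismatch;
}

// Global (Needleman-Wunsch) alignment, linear gap penalty. Among all
// score-optimal alignments the one with the fewest gap runs is returned
// (lexicographic objective via a three-state Gotoh-style DP), so a planted
// contiguous indel is reported as one gap run rather than interleaved with
// chance matches. Remaining ties prefer the diagonal state, then gaps in b,
// then gaps in a.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  // states: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
  std::vector< std::vector< std::array<double, 3> > >
    S(n + 1, std::vector< std::array<double, 3> >(m + 1));
  std::vector< std::vector< std::array<int, 3> > >
    R(n + 1, std::vector< std::array<int, 3> >(m + 1));      // gap-run counts
  std::vector< std::vector< std::array<int, 3> > >
    G(n + 1, std::vector< std::array<int, 3> >(m + 1));      // gap-column counts
  std::vector< std::vector< std::array<signed char, 3> > >
    P(n + 1, std::vector< std::array<signed char, 3> >(m + 1)); // pred state
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j)
      for (int s = 0; s < 3; ++s) {
        S[i][j][s] = NEG; R[i][j][s] = 0; G[i][j][s] = 0; P[i][j][s] = -1;
      }
  S[0][0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    S[i][0][1] = i * gap; R[i][0][1] = 1; G[i][0][1] = i;
    P[i][0][1] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    S[0][j][2] = j * gap; R[0][j][2] = 1; G[0][j][2] = j;
    P[0][j][2] = (j == 1) ? 0 : 2;
  }
  // candidate better than current best? lexicographic: score, then fewer
  // gap columns (prefer substitutions over indel pairs), then fewer gap runs
  auto better = [](double cs, int cg, int cr, double bs, int bg, int br) {
    if (cs > bs + 1e-9) return true;
    if (cs < bs - 1e-9) return false;
    if (cg != bg) return cg < bg;
    return cr < br;
  };
  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      if (i == 0 && j == 0) continue;
      if (i > 0 && j > 0) {  // M state
        double sub = subscore(a[i - 1], b[j - 1], match, mismatch);
        for (int s = 0; s < 3; ++s) {
          if (S[i - 1][j - 1][s] <= NEG / 2) continue;
          double cs = S[i - 1][j - 1][s] + sub;
          int cr = R[i - 1][j - 1][s];
          int cg = G[i - 1][j - 1][s];
          if (P[i][j][0] < 0 ||
              better(cs, cg, cr, S[i][j][0], G[i][j][0], R[i][j][0])) {
            S[i][j][0] = cs; R[i][j][0] = cr; G[i][j][0] = cg;
            P[i][j][0] = (signed char) s;
          }
        }
      }
      if (i > 0) {           // X state: gap in b
        for (int s = 0; s < 3; ++s) {
          if (S[i - 1][j][s] <= NEG / 2) continue;
          double cs = S[i - 1][j][s] + gap;
          int cr = R[i - 1][j][s] + (s == 1 ? 0 : 1);
          int cg = G[i - 1][j][s] + 1;
          // prefer extension (s == 1) on full ties
          if (P[i][j][1] < 0 ||
              better(cs, cg, cr, S[i][j][1], G[i][j][1], R[i][j][1]) ||
              (cs > S[i][j][1] - 1e-9 && cg == G[i][j][1] &&
               cr == R[i][j][1] && s == 1)) {
            S[i][j][1] = cs; R[i][j][1] = cr; G[i][j][1] = cg;
            P[i][j][1] = (signed char) s;
          }
        }
      }
      if (j > 0) {           // Y state: gap in a
        for (int s = 0; s < 3; ++s) {
          if (S[i][j - 1][s] <= NEG / 2) continue;
          double cs = S[i][j - 1][s] + gap;
          int cr = R[i][j - 1][s] + (s == 2 ? 0 : 1);
          int cg = G[i][j - 1][s] + 1;
          if (P[i][j][2] < 0 ||
              better(cs, cg, cr, S[i][j][2], G[i][j][2], R[i][j][2]) ||
              (cs > S[i][j][2] - 1e-9 && cg == G[i][j][2] &&
               cr == R[i][j][2] && s == 2)) {
            S[i][j][2] = cs; R[i][j][2] = cr; G[i][j][2] = cg;
            P[i][j][2] = (signed char) s;
          }
        }
      }
    }
  }
  int state = 0;
  for (int s = 1; s < 3; ++s) {
    if (P[n][m][state] < 0 ||
        (P[n][m][s] >= 0 && better(S[n][m][s], G[n][m][s], R[n][m][s],
                                   S[n][m][state], G[n][m][state],
                                   R[n][m][state]))) {
      state = s;
    }
  }
  double score = S[n][m][state];
  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev = P[i][j][state];
    if (state == 0) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (state == 1) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    }
    state = prev;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = score, _["a"] = aa, _["b"] = bb);
}

// Local (Smith-Waterman) alignment, linear gap penalty. The best cell is the
// first maximum in row-major order; traceback prefers diagonal, up, left.
// Returned coordinates are 1-based inclusive on each input.
// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S(i - 1, j - 1) + subscore(a[i - 1], b[j - 1], match, mismatch);
      double u = S(i - 1, j) + gap;
      double l = S(i, j - 1) + gap;
      double v = std::max(0.0, std::max(d, std::max(u, l)));
      S(i, j) = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a"] = "", _["b"] = "",
                        _["start_a"] = NA_INTEGER, _["end_a"] = NA_INTEGER,
                        _["start_b"] = NA_INTEGER, _["end_b"] = NA_INTEGER);
  }
  std::string aa, bb;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && S(i, j) > 0.0) {
    if (S(i, j) == S(i - 1, j - 1) + subscore(a[i - 1], b[j - 1], match, mismatch)) {
      aa.push_back(a[i - 1]); bb.push_back(b[j - 1]); --i; --j;
    } else if (S(i, j) == S(i - 1, j) + gap) {
      aa.push_back(a[i - 1]); bb.push_back('-'); --i;
    } else if (S(i, j) == S(i, j - 1) + gap) {
      aa.push_back('-'); bb.push_back(b[j - 1]); --j;
    } else {
      break;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = best, _["a"] = aa, _["b"] = bb,
                      _["start_a"] = i + 1, _["end_a"] = bi,
                      _["start_b"] = j + 1, _["end_b"] = bj);
}
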