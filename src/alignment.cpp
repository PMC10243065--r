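#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Banded Smith-Waterman with affine gap costs and full traceback.
// Cells with |i - j| > band are outside the band and unreachable.
// gap_open / gap_extend are costs (>= 0); a gap of length g costs
// gap_open + g * gap_extend.  Traceback tie order: diagonal, then gap in s1
// (consume s2), then gap in s2, which makes results deterministic.

static const int NEG = -1000000000;

// [[Rcpp::export]]
List banded_local_align_cpp(std::string s1, std::string s2,
                            int match, int mismatch,
                            int gap_open, int gap_extend, int band) {
  const int n = (int) s1.size();
  const int m = (int) s2.size();
  const int W = m + 1;
  std::vector<int> H((size_t)(n + 1) * W, 0), E((size_t)(n + 1) * W, NEG),
      F((size_t)(n + 1) * W, NEG);
  // traceback state: for H: 0 stop, 1 diag, 2 from E, 3 from F
  // for E: 0 opened from H, 1 extended; same for F
  std::vector<unsigned char> tbH((size_t)(n + 1) * W, 0),
      tbE((size_t)(n + 1) * W, 0), tbF((size_t)(n + 1) * W, 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      size_t c = (size_t) i * W + j;
      size_t up = c - W, left = c - 1, diag = c - W - 1;
      // E: gap in s1, consume s2[j-1] (move left)
      if (j - 1 >= i - band) {  // left neighbour inside band
        int opn = H[left] - gap_open - gap_extend;
        int ext = E[left] - gap_extend;
        if (opn >= ext) { E[c] = opn; tbE[c] = 0; } else { E[c] = ext; tbE[c] = 1; }
      }
      // F: gap in s2, consume s1[i-1] (move up)
      if (j + band >= i - 1 && j <= (i - 1) + band) {  // up neighbour inside band
        int opn = H[up] - gap_open - gap_extend;
        int ext = F[up] - gap_extend;
        if (opn >= ext) { F[c] = opn; tbF[c] = 0; } else { F[c] = ext; tbF[c] = 1; }
      }
      int sub = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
      int dg = H[diag] + sub;  // H outside band is 0 only at j==i±band edges;
      // guard: diag neighbour outside band would wrongly contribute 0, but
      // |i-1 - (j-1)| == |i-j| <= band, so diag is always inside (or border 0).
      int v = 0; unsigned char t = 0;
      if (dg >= v) { v = dg; t = 1; }
      if (E[c] > v) { v = E[c]; t = 2; }
      if (F[c] > v) { v = F[c]; t = 3; }
      if (dg >= v && dg >= 1) { v = dg; t = 1; }  // prefer diagonal on ties
      H[c] = v; tbH[c] = (v > 0) ? t : 0;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  // traceback
  std::string ops;  // reversed
  int i = bi, j = bj, nmatch = 0;
  char state = 'H';
  while (i > 0 && j > 0) {
    size_t c = (size_t) i * W + j;
    if (state == 'H') {
      unsigned char t = tbH[c];
      if (t == 0) break;
      if (t == 1) {
        ops.push_back(s1[i - 1] == s2[j - 1] ? 'M' : 'X');
        if (s1[i - 1] == s2[j - 1]) ++nmatch;
        --i; --j;
      } else if (t == 2) state = 'E';
      else state = 'F';
    } else if (state == 'E') {
      ops.push_back('I');  // gap in s1, consumes s2
      unsigned char t = tbE[c];
      --j;
      state = (t == 1) ? 'E' : 'H';
    } else {
      ops.push_back('D');  // gap in s2, consumes s1
      unsigned char t = tbF[c];
      --i;
      state = (t == 1) ? 'F' : 'H';
    }
  }
  std::reverse(ops.begin(), ops.end());
  int b1 = 0, e1 = 0, b2 = 0, e2 = 0;
  if (best > 0) { b1 = i + 1; e1 = bi; b2 = j + 1; e2 = bj; }
  return List::create(_["score"] = best,
                      _["begin1"] = b1, _["end1"] = e1,
                      _["begin2"] = b2, _["end2"] = e2,
                      _["n_perfect"] = nmatch,
                      _["trace"] = ops);
}

// Global Needleman-Wunsch score with linear gap costs
// (match +1, mismatch -1, gap -1 by default).  Score only, two-row DP.

// [[Rcpp::export]]
int global_align_score_cpp(std::string s1, std::string s2,
                           int match = 1, int mismatch = -1, int gap = -1) {
  const int n = (int) s1.size();
  const int m = (int) s2.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= m; ++j) {
      int sub = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
      int v = prev[j - 1] + sub;
      int up = prev[j] + gap;
      int left = cur[j - 1] + gap;
      if (up > v) v = up;
      if (left > v) v = left;
      cur[j] = v;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
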