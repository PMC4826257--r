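#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Optimal Smith-Waterman local alignment score with affine gaps (Gotoh,
// linear memory). a and b are 0-based indices into the rows/cols of S.
// A gap of length L costs gap_open + L * gap_extend, so a length-1 gap
// costs gap_open + gap_extend (BLAST convention). The empty alignment is
// allowed, hence the score is always >= 0.
static int sw_one(const std::vector<int>& a, const std::vector<int>& b,
                  const IntegerMatrix& S, int gap_open, int gap_extend) {
  const int m = (int)a.size(), n = (int)b.size();
  const int NEG = INT_MIN / 4;
  std::vector<int> H(n + 1, 0), E(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;       // H[i-1][j-1]
    int Hleft = 0;       // H[i][j-1]
    int F = NEG;         // gap in b ending at column j
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(E[j] - gap_extend, H[j] - gap_open - gap_extend);
      F = std::max(F - gap_extend, Hleft - gap_open - gap_extend);
      int h = Hdiag + S(a[i - 1], b[j - 1]);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0);
      Hdiag = H[j];
      H[j] = h;
      Hleft = h;
      if (h > best) best = h;
    }
  }
  return best;
}

static std::vector<int> as_vec(const IntegerVector& x) {
  return std::vector<int>(x.begin(), x.end());
}

// [[Rcpp::export(name = ".sw_score_cpp")]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                 int gap_open, int gap_extend) {
  return sw_one(as_vec(a), as_vec(b), S, gap_open, gap_extend);
}

// Batch interface: pairs of encoded sequences, one score per pair.
// [[Rcpp::export(name = ".sw_scores_cpp")]]
IntegerVector sw_scores_cpp(List a_list, List b_list, IntegerMatrix S,
                            int gap_open, int gap_extend) {
  const int k = a_list.size();
  IntegerVector out(k);
  for (int i = 0; i < k; ++i) {
    out[i] = sw_one(as_vec(a_list[i]), as_vec(b_list[i]), S,
                    gap_open, gap_extend);
  }
  return out;
}
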