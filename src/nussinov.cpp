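#include <Rcpp.h>
#include <string>
#include <vector>

// Allowed pairs: Watson-Crick (A-T, G-C) plus wobble G-T. Input is
// upper-case DNA alphabet (U already mapped to T by the caller).
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

//' Maximum number of nested base pairs (Nussinov dynamic programme)
//'
//' Computes the maximum number of non-crossing base pairs over a sequence,
//' with a minimum hairpin loop of `min_loop` unpaired bases between any
//' paired positions. Used as the dimensionless folding-energy proxy
//' (-1 pseudo-energy per pair).
//'
//' @param seq Upper-case DNA string (T, not U).
//' @param min_loop Minimum number of unpaired bases enclosed by a pair.
//' @return Integer: maximal pair count.
//' @keywords internal
// [[Rcpp::export]]
int nussinov_pairs(std::string seq, int min_loop) {
  int n = seq.size();
  if (n < min_loop + 2) return 0;
  // dp[i][j] stored in a flat vector, 0-based inclusive indices
  std::vector<int> dp((size_t)n * n, 0);
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = dp[(size_t)i * n + (j - 1)];           // j unpaired
      if (can_pair(seq[i], seq[j]) && j - i > min_loop) {
        int inner = (i + 1 <= j - 1) ? dp[(size_t)(i + 1) * n + (j - 1)] : 0;
        int cand = inner + 1;
        if (cand > best) best = cand;
      }
      // j paired with some k in (i, j)
      for (int k = i + 1; k < j; ++k) {
        if (can_pair(seq[k], seq[j]) && j - k > min_loop) {
          int left = dp[(size_t)i * n + (k - 1)];
          int inner = (k + 1 <= j - 1) ? dp[(size_t)(k + 1) * n + (j - 1)] : 0;
          int cand = left + inner + 1;
          if (cand > best) best = cand;
        }
      }
      dp[(size_t)i * n + j] = best;
    }
  }
  return dp[(size_t)0 * n + (n - 1)];
}
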