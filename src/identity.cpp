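#include <Rcpp.h>
#include <string>
#include <vector>

// Length of the longest common subsequence of two strings: the score of an
// optimal global alignment under match = 1, mismatch = 0, gap = 0.
// [[Rcpp::export]]
int lcs_length_cpp(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) {
        cur[j] = prev[j - 1] + 1;
      } else {
        cur[j] = std::max(prev[j], cur[j - 1]);
      }
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
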