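#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalties.
// Traceback ties broken deterministically: diagonal, then up (gap in b),
// then left (gap in a), so identical inputs always give identical output.

static inline int score3(char a, char b, int match, int mismatch) {
  return a == b ? match : mismatch;
}

// [[Rcpp::export(name = ".nw_score")]]
int nw_score(std::string a, std::string b, int match = 1, int mismatch = -1,
             int gap = -2) {
  const int m = a.size(), n = b.size();
  std::vector<int> prev(n + 1), cur(n + 1);
  for (int j = 0; j <= n; ++j) prev[j] = j * gap;
  for (int i = 1; i <= m; ++i) {
    cur[0] = i * gap;
    for (int j = 1; j <= n; ++j) {
      int d = prev[j - 1] + score3(a[i - 1], b[j - 1], match, mismatch);
      int u = prev[j] + gap;
      int l = cur[j - 1] + gap;
      cur[j] = d >= u ? (d >= l ? d : l) : (u >= l ? u : l);
    }
    std::swap(prev, cur);
  }
  return prev[n];
}

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(std::string a, std::string b, int match = 1, int mismatch = -1,
              int gap = -2) {
  const int m = a.size(), n = b.size();
  NumericMatrix H(m + 1, n + 1);
  for (int i = 0; i <= m; ++i) H(i, 0) = i * gap;
  for (int j = 0; j <= n; ++j) H(0, j) = j * gap;
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      double d = H(i - 1, j - 1) + score3(a[i - 1], b[j - 1], match, mismatch);
      double u = H(i - 1, j) + gap;
      double l = H(i, j - 1) + gap;
      H(i, j) = std::max(d, std::max(u, l));
    }
  std::string ra, rb;
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        H(i, j) == H(i - 1, j - 1) + score3(a[i - 1], b[j - 1], match, mismatch)) {
      ra += a[i - 1]; rb += b[j - 1]; --i; --j;
    } else if (i > 0 && H(i, j) == H(i - 1, j) + gap) {
      ra += a[i - 1]; rb += '-'; --i;
    } else {
      ra += '-'; rb += b[j - 1]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = (int)H(m, n));
}

// Summed pairwise NW scores of every sequence against every other;
// used to pick the center read of the star alignment.
// [[Rcpp::export(name = ".nw_score_sums")]]
NumericVector nw_score_sums(CharacterVector seqs, int match = 1,
                            int mismatch = -1, int gap = -2) {
  const int n = seqs.size();
  NumericVector sums(n);
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      int sc = nw_score(s[i], s[j], match, mismatch, gap);
      sums[i] += sc;
      sums[j] += sc;
    }
  return sums;
}
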