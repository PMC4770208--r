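#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global alignment with free terminal gaps (overlap / semi-global mode):
// first row and column are initialised to zero and the optimum is taken over
// the last row and column, so unaligned mate tails carry no penalty.  Linear
// gap cost.  Traceback tie-breaking is fixed for determinism: diagonal, then
// up (consume s1 against a gap), then left.  The end cell is chosen by
// scanning (m,n), then the last row right-to-left, then the last column
// bottom-to-top, keeping the first maximum.
// [[Rcpp::export(name = ".nw_overlap")]]
List nw_overlap_c(std::string s1, std::string s2,
                  double match, double mismatch, double gap) {
  const int m = s1.size(), n = s2.size();
  if (m == 0 || n == 0) stop("sequences must be non-empty");

  std::vector<std::vector<double> > S(m + 1, std::vector<double>(n + 1, 0.0));
  std::vector<std::vector<char> > T(m + 1, std::vector<char>(n + 1, 0));
  for (int i = 1; i <= m; ++i) T[i][0] = 1;  // up
  for (int j = 1; j <= n; ++j) T[0][j] = 2;  // left

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double sub = (s1[i - 1] == s2[j - 1]) ? match : mismatch;
      double best = S[i - 1][j - 1] + sub;
      char dir = 0;
      const double up = S[i - 1][j] + gap;
      if (up > best) { best = up; dir = 1; }
      const double left = S[i][j - 1] + gap;
      if (left > best) { best = left; dir = 2; }
      S[i][j] = best;
      T[i][j] = dir;
    }
  }

  int bi = m, bj = n;
  double bestScore = S[m][n];
  for (int j = n - 1; j >= 0; --j)
    if (S[m][j] > bestScore) { bestScore = S[m][j]; bi = m; bj = j; }
  for (int i = m - 1; i >= 0; --i)
    if (S[i][n] > bestScore) { bestScore = S[i][n]; bi = i; bj = n; }

  std::string a1, a2;
  // trailing free end gaps
  for (int i = m; i > bi; --i) { a1 += s1[i - 1]; a2 += '-'; }
  for (int j = n; j > bj; --j) { a1 += '-'; a2 += s2[j - 1]; }

  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    const char dir = T[i][j];
    if (dir == 0) { a1 += s1[i - 1]; a2 += s2[j - 1]; --i; --j; }
    else if (dir == 1) { a1 += s1[i - 1]; a2 += '-'; --i; }
    else { a1 += '-'; a2 += s2[j - 1]; --j; }
  }

  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());

  return List::create(_["aligned1"] = a1,
                      _["aligned2"] = a2,
                      _["score"] = bestScore);
}
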