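#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Error-count distribution of a read by iterated Bernoulli convolution.
// Each base i is right with probability 1 - p[i] and wrong with p[i]; the
// number of wrong bases S_N is Poisson binomial.  Because each Bernoulli
// variable only takes values {0, 1}, one convolution step reduces to
//   new[j] = old[j] * (1 - p_i) + old[j - 1] * p_i.
// Terms above j_cap are never stored, so the cost is O(N * j_cap).
// [[Rcpp::export(name = ".pbf_distribution")]]
NumericVector pbf_distribution_c(NumericVector p, int j_cap) {
  const int n = p.size();
  if (j_cap < 0 || j_cap > n) stop("j_cap must lie in [0, length(probs)]");
  NumericVector u(j_cap + 1);
  u[0] = 1.0;
  int hi = 0;  // largest index with support after i bases
  for (int i = 0; i < n; ++i) {
    const double pi = p[i];
    if (pi < 0.0 || pi > 1.0) stop("per-base error probabilities must lie in [0, 1]");
    const int new_hi = std::min(hi + 1, j_cap);
    for (int j = new_hi; j >= 1; --j)
      u[j] = u[j] * (1.0 - pi) + u[j - 1] * pi;
    u[0] *= (1.0 - pi);
    hi = new_hi;
  }
  return u;
}

// Lazy computation of the confidence quantile j_xi.  The pmf terms
// P(S_N = j) are produced one j at a time, each by a single O(N) sweep of
// the recursion P(S_i = j) = P(S_{i-1} = j)(1 - p_i) + P(S_{i-1} = j-1) p_i,
// stopping at the first j_max whose cumulative sum reaches xi.  Terms beyond
// j_max are never computed.  The quantile is linearly interpolated between
// j_max - 1 and j_max:
//   j_xi = j_max - 1 + (xi - cum(j_max - 1)) / P(S_N = j_max),
// clamped to [0, N].
// [[Rcpp::export(name = ".pbf_jxi")]]
List pbf_jxi_c(NumericVector p, double xi) {
  const int n = p.size();
  if (n == 0) stop("probs must be non-empty");
  if (!(xi > 0.0 && xi < 1.0)) stop("xi must lie in (0, 1)");
  for (int i = 0; i < n; ++i)
    if (p[i] < 0.0 || p[i] > 1.0) stop("per-base error probabilities must lie in [0, 1]");

  std::vector<double> prev(n + 1), cur(n + 1);
  prev[0] = 1.0;
  for (int i = 1; i <= n; ++i) prev[i] = prev[i - 1] * (1.0 - p[i - 1]);

  std::vector<double> probs;
  probs.push_back(prev[n]);      // P(S_N = 0)
  double cum = prev[n];
  int j = 0;
  while (cum < xi && j < n) {
    ++j;
    cur[0] = 0.0;
    for (int i = 1; i <= n; ++i)
      cur[i] = cur[i - 1] * (1.0 - p[i - 1]) + prev[i - 1] * p[i - 1];
    std::swap(prev, cur);
    probs.push_back(prev[n]);    // P(S_N = j)
    cum += prev[n];
  }

  const double pj = probs[j];
  double jxi;
  if (pj <= 0.0) {
    // cumulative reached xi exactly at an earlier term whose own mass
    // underflowed; fall back to the integer stopping point
    jxi = (double)j;
  } else {
    jxi = (double)j - 1.0 + (xi - (cum - pj)) / pj;
  }
  if (jxi < 0.0) jxi = 0.0;
  if (jxi > (double)n) jxi = (double)n;

  return List::create(_["jxi"] = jxi,
                      _["j_max"] = j,
                      _["probs"] = NumericVector(probs.begin(), probs.end()));
}
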