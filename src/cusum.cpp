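#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Best split of each candidate interval by |CUSUM|, smallest split on ties.
// standard: CUSUM of x itself (one pass of global cumulative sums);
// robust:   CUSUM of sign(x - median(x[s:e])), median recomputed per interval.
// Indices are 1-based inclusive. Returns an m x 3 matrix: b, contrast, |contrast|.
// [[Rcpp::export]]
NumericMatrix cusum_best_cpp(NumericVector x, IntegerVector s, IntegerVector e,
                             bool robust) {
  const int T = x.size(), m = s.size();
  NumericMatrix out(m, 3);
  std::vector<double> cs;
  if (!robust) {
    cs.assign(T + 1, 0.0);
    for (int t = 0; t < T; ++t) cs[t + 1] = cs[t] + x[t];
  }
  std::vector<double> lcs, tmp;
  for (int i = 0; i < m; ++i) {
    const int a = s[i], z = e[i];
    const int n = z - a + 1;
    const double nn = (double)n;
    double best = -1.0, bestc = 0.0;
    int bestb = a;
    if (robust) {
      // interval median: mean of the two central order statistics when n is even
      tmp.assign(x.begin() + (a - 1), x.begin() + z);
      const int h = n / 2;
      std::nth_element(tmp.begin(), tmp.begin() + h, tmp.end());
      double med = tmp[h];
      if (n % 2 == 0) {
        std::nth_element(tmp.begin(), tmp.begin() + h - 1, tmp.begin() + h);
        med = 0.5 * (tmp[h - 1] + med);
      }
      lcs.assign(n + 1, 0.0);
      for (int t = 0; t < n; ++t) {
        const double d = x[a - 1 + t] - med;
        lcs[t + 1] = lcs[t] + ((d > 0) - (d < 0));
      }
      // mean form sqrt(nl*nr/n)*(mean_l - mean_r): algebraically identical to
      // the sum form, but exactly zero on constant segments (no sqrt residue)
      for (int b = a; b < z; ++b) {
        const double nl = b - a + 1, nr = z - b;
        const double L = lcs[b - a + 1], R = lcs[n] - L;
        const double c = std::sqrt(nl * nr / nn) * (L / nl - R / nr);
        const double ac = std::fabs(c);
        if (ac > best) { best = ac; bestc = c; bestb = b; }
      }
    } else {
      for (int b = a; b < z; ++b) {
        const double nl = b - a + 1, nr = z - b;
        const double L = cs[b] - cs[a - 1], R = cs[z] - cs[b];
        const double c = std::sqrt(nl * nr / nn) * (L / nl - R / nr);
        const double ac = std::fabs(c);
        if (ac > best) { best = ac; bestc = c; bestb = b; }
      }
    }
    out(i, 0) = bestb;
    out(i, 1) = bestc;
    out(i, 2) = best;
  }
  return out;
}
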