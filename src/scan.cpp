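#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive maximal-scoring interval search.
//
// Scans every contiguous interval [i, j] of the probe values r and returns
// the one maximizing |sum(r[i..j])| / sqrt(j - i + 1).  The returned score
// is divided by sigma so that score = |S| / (sigma * sqrt(k)).  Ties are
// broken toward the longer interval, then the leftmost.  Indices are 1-based.
//
// [[Rcpp::export(name = ".scan_exhaustive")]]
List scan_exhaustive(NumericVector r, double sigma) {
  const int n = r.size();
  if (n < 1) stop("empty probe vector");
  std::vector<double> S(n + 1, 0.0);
  for (int i = 0; i < n; ++i) S[i + 1] = S[i] + r[i];
  std::vector<double> isq(n + 1, 0.0);
  for (int k = 1; k <= n; ++k) isq[k] = 1.0 / std::sqrt((double)k);

  double best = -1.0;
  int bi = 0, bj = 0, blen = 0;
  for (int i = 0; i < n; ++i) {
    const double Si = S[i];
    for (int j = i; j < n; ++j) {
      const int len = j - i + 1;
      double sc = std::fabs(S[j + 1] - Si) * isq[len];
      double tol = 1e-12 * (1.0 + best);
      if (sc > best + tol) {
        best = sc; bi = i; bj = j; blen = len;
      } else if (sc >= best - tol) {
        // tie: prefer longer, then leftmost
        if (len > blen || (len == blen && i < bi)) {
          best = std::max(best, sc); bi = i; bj = j; blen = len;
        }
      }
    }
  }
  return List::create(_["i"] = bi + 1, _["j"] = bj + 1,
                      _["score"] = best / sigma);
}
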