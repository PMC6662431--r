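#include <Rcpp.h>
using namespace Rcpp;

// Global alignment with free end gaps under unit scoring
// (match +1, mismatch 0, gap -1).  Identity is matches over
// alignment columns between the first and last aligned pair
// (terminal-gap columns excluded); coverage is the aligned span
// of each sequence over its length.
//
// Tie-breaking is fixed so results are deterministic: during the
// fill, diagonal moves are preferred over up (gap in target) over
// left (gap in query); for the end cell, (n,m) is preferred, then
// the last column top-to-bottom, then the last row left-to-right,
// replacing only on a strictly better score.
// [[Rcpp::export(name = ".alignFreeEndGaps")]]
List alignFreeEndGaps(std::string query, std::string target) {
  const int n = query.size(), m = target.size();
  if (n == 0 || m == 0)
    stop("empty sequence");
  std::vector<double> S((n + 1) * (m + 1), 0.0);
  std::vector<unsigned char> P((n + 1) * (m + 1), 0); // 0 diag, 1 up, 2 left
  const int W = m + 1;
  for (int i = 0; i <= n; ++i) P[i * W] = 1;
  for (int j = 0; j <= m; ++j) P[j] = 2;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = S[(i - 1) * W + (j - 1)] + (query[i - 1] == target[j - 1] ? 1.0 : 0.0);
      double u = S[(i - 1) * W + j] - 1.0;
      double l = S[i * W + (j - 1)] - 1.0;
      double best = d; unsigned char p = 0;
      if (u > best) { best = u; p = 1; }
      if (l > best) { best = l; p = 2; }
      S[i * W + j] = best; P[i * W + j] = p;
    }
  }
  int bi = n, bj = m;
  double best = S[n * W + m];
  for (int i = 0; i <= n; ++i)
    if (S[i * W + m] > best) { best = S[i * W + m]; bi = i; bj = m; }
  for (int j = 0; j <= m; ++j)
    if (S[n * W + j] > best) { best = S[n * W + j]; bi = n; bj = j; }
  int i = bi, j = bj, matches = 0, cols = 0;
  while (i > 0 && j > 0) {
    unsigned char p = P[i * W + j];
    if (p == 0) {
      if (query[i - 1] == target[j - 1]) ++matches;
      ++cols; --i; --j;
    } else if (p == 1) {
      ++cols; --i;
    } else {
      ++cols; --j;
    }
  }
  const int qSpan = bi - i, tSpan = bj - j;
  return List::create(
    _["identity"] = cols > 0 ? (double)matches / cols : 0.0,
    _["query_cov"] = (double)qSpan / n,
    _["target_cov"] = (double)tSpan / m,
    _["matches"] = matches,
    _["columns"] = cols,
    _["score"] = best);
}
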