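#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with the three-neighbour recursion
//   D(i,j) = |a_i - b_j| + min(D(i-1,j), D(i,j-1), D(i-1,j-1))
// under an optional global constraint. ctype: 0 none, 1 Sakoe-Chiba band
// (|i*n/m - j| <= band, in index units), 2 Itakura parallelogram (slope
// bounds 1/2 and 2 from both corners). Returns the accumulated cost and the
// backtracked optimal path; ties in backtracking prefer the diagonal step,
// then the (i-1,j) step, so the path is deterministic.
// [[Rcpp::export]]
List dtw_core(NumericVector a, NumericVector b, int ctype, double band) {
  const int m = a.size(), n = b.size();
  const double INF = R_PosInf;
  NumericMatrix D(m, n);

  auto allowed = [&](int i, int j) -> bool {  // 0-based
    if (ctype == 1) {
      double diag = (m == 1) ? 0.0 : (double)i * (n - 1) / (m - 1);
      return std::fabs(diag - j) <= band;
    }
    if (ctype == 2) {
      // slope constraints from (0,0) and (m-1,n-1)
      return (j <= 2 * i) && (i <= 2 * j) &&
             ((m - 1 - i) <= 2 * (n - 1 - j)) &&
             ((n - 1 - j) <= 2 * (m - 1 - i));
    }
    return true;
  };

  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      if (!allowed(i, j)) { D(i, j) = INF; continue; }
      double c = std::fabs(a[i] - b[j]);
      if (i == 0 && j == 0) { D(i, j) = c; continue; }
      double best = INF;
      if (i > 0 && j > 0 && D(i - 1, j - 1) < best) best = D(i - 1, j - 1);
      if (i > 0 && D(i - 1, j) < best) best = D(i - 1, j);
      if (j > 0 && D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = (best == INF) ? INF : c + best;
    }
  }

  double cost = D(m - 1, n - 1);
  if (!R_finite(cost)) {
    return List::create(_["cost"] = cost, _["path_i"] = IntegerVector(0),
                        _["path_j"] = IntegerVector(0));
  }

  std::vector<int> pi, pj;
  int i = m - 1, j = n - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    double dd = (i > 0 && j > 0) ? D(i - 1, j - 1) : INF;
    double du = (i > 0) ? D(i - 1, j) : INF;
    double dl = (j > 0) ? D(i, j - 1) : INF;
    if (dd <= du && dd <= dl) { --i; --j; }
    else if (du <= dl) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = cost, _["path_i"] = wrap(pi),
                      _["path_j"] = wrap(pj));
}
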