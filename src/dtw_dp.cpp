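#include <Rcpp.h>
using namespace Rcpp;

// Banded dynamic program over a precomputed local-cost matrix with the
// symmetric step pattern (1,0), (0,1), (1,1). Minimizes the path SUM of
// local costs from (1,1) to (M,N); backtracking tie-break prefers the
// diagonal step, then the step advancing the first (X) index.
// window = allowed |i - j| (may be R_PosInf for an unconstrained path).
// [[Rcpp::export]]
List dtw_dp(NumericMatrix cost, double window) {
  const int M = cost.nrow(), N = cost.ncol();
  const double INF = R_PosInf;
  NumericMatrix D(M, N);
  IntegerMatrix from(M, N); // 0 = diag, 1 = (i-1,j), 2 = (i,j-1), -1 = start/invalid

  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < N; ++j) {
      if (std::abs(i - j) > window) {
        D(i, j) = INF;
        from(i, j) = -1;
        continue;
      }
      if (i == 0 && j == 0) {
        D(i, j) = cost(i, j);
        from(i, j) = -1;
        continue;
      }
      double dd = (i > 0 && j > 0) ? D(i - 1, j - 1) : INF;
      double du = (i > 0) ? D(i - 1, j) : INF;
      double dl = (j > 0) ? D(i, j - 1) : INF;
      double best = dd;
      int arg = 0;
      if (du < best) { best = du; arg = 1; }
      if (dl < best) { best = dl; arg = 2; }
      if (best == INF) {
        D(i, j) = INF;
        from(i, j) = -1;
      } else {
        D(i, j) = best + cost(i, j);
        from(i, j) = arg;
      }
    }
  }

  if (!R_FINITE(D(M - 1, N - 1))) {
    return List::create(Named("feasible") = false);
  }

  std::vector<int> a, b;
  int i = M - 1, j = N - 1;
  a.push_back(i + 1);
  b.push_back(j + 1);
  while (i > 0 || j > 0) {
    int step = from(i, j);
    if (step == 0) { --i; --j; }
    else if (step == 1) { --i; }
    else { --j; }
    a.push_back(i + 1);
    b.push_back(j + 1);
  }
  std::reverse(a.begin(), a.end());
  std::reverse(b.begin(), b.end());

  return List::create(
    Named("feasible") = true,
    Named("a") = wrap(a),
    Named("b") = wrap(b),
    Named("cost_sum") = D(M - 1, N - 1));
}
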