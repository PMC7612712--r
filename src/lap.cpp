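#include <Rcpp.h>
#include <vector>
#include <limits>

// Jonker-Volgenant shortest augmenting path solver for the dense square
// linear assignment problem (minimise total cost).  Costs marked >= big are
// treated as forbidden.  Returns, for each row, the assigned column
// (1-based).  Deterministic: rows are augmented in index order and equal
// reduced costs resolve to the lowest column index.
// [[Rcpp::export]]
Rcpp::IntegerVector lap_solve(Rcpp::NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) Rcpp::stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0);    // p[j] = row assigned to column j (1-based)
  std::vector<int> way(n + 1, 0);

  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do {
      int j1 = way[j0];
      p[j0] = p[j1];
      j0 = j1;
    } while (j0);
  }

  Rcpp::IntegerVector assign(n);
  for (int j = 1; j <= n; ++j) assign[p[j] - 1] = j;
  return assign;
}
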