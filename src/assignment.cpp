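#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

//' Solve a square linear assignment problem
//'
//' Minimizes the total cost of a one-to-one row/column assignment with the
//' O(n^3) shortest-augmenting-path algorithm (Jonker-Volgenant style, dual
//' potentials). Used to re-match perturbed to unperturbed modes by passing
//' the negated squared overlap matrix as the cost.
//'
//' @param cost square numeric cost matrix.
//' @return integer vector: for each row, the 1-based assigned column.
//' @export
// [[Rcpp::export]]
IntegerVector solve_assignment(NumericMatrix cost) {
  const int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
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
  IntegerVector ans(n);
  for (int j = 1; j <= n; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
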