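#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Minimum spanning tree of the complete mutual-reachability graph of a 2D
// point set: w(i,j) = max(core[i], core[j], ||p_i - p_j||). Prim's algorithm
// with on-the-fly distance evaluation, O(n^2) time and O(n) memory, which is
// the standard approach for dense low-dimensional SMLM data.
//
// Returns an (n-1) x 3 matrix with 1-based endpoint columns and the edge
// weight; edges appear in tree-growth order.
// [[Rcpp::export]]
NumericMatrix mst_mutual_reachability(NumericMatrix coords,
                                      NumericVector core) {
  const int n = coords.nrow();
  if (n < 2) return NumericMatrix(0, 3);
  std::vector<double> best(n, R_PosInf);
  std::vector<int> from(n, -1);
  std::vector<bool> inTree(n, false);
  NumericMatrix edges(n - 1, 3);

  int cur = 0;
  inTree[0] = true;
  for (int e = 0; e < n - 1; ++e) {
    const double cx = coords(cur, 0), cy = coords(cur, 1);
    const double ccore = core[cur];
    for (int j = 0; j < n; ++j) {
      if (inTree[j]) continue;
      const double dx = coords(j, 0) - cx, dy = coords(j, 1) - cy;
      double w = std::sqrt(dx * dx + dy * dy);
      if (ccore > w) w = ccore;
      if (core[j] > w) w = core[j];
      if (w < best[j]) { best[j] = w; from[j] = cur; }
    }
    double wmin = R_PosInf;
    int jmin = -1;
    for (int j = 0; j < n; ++j)
      if (!inTree[j] && best[j] < wmin) { wmin = best[j]; jmin = j; }
    edges(e, 0) = from[jmin] + 1;
    edges(e, 1) = jmin + 1;
    edges(e, 2) = wmin;
    inTree[jmin] = true;
    cur = jmin;
  }
  return edges;
}
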