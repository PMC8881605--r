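#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Regression tree growth with exhaustive SSE-minimising binary splits.
// Split criterion: minimise SSE(left) + SSE(right), i.e. the sum of squared
// differences from the partition means (variance-reduction splitting).
// Nodes stop splitting when the node is pure (SSE ~ 0), smaller than twice
// the minimum leaf size, at max depth, or when no admissible split improves
// the SSE. mtry < p draws a random feature subset per node using R's RNG
// stream (seed controlled from the R side with set.seed()).

struct Node {
  int feature;      // -1 for leaf (0-based feature index otherwise)
  double threshold; // x <= threshold goes left
  int left, right;  // 0-based node indices, -1 for leaf
  double value;     // node mean
};

static void grow(const NumericMatrix& X, const NumericVector& y,
                 std::vector<int>& rows, int depth,
                 int min_node, int max_depth, int mtry,
                 std::vector<Node>& nodes, int node_id) {
  const int n = rows.size();
  double sum = 0.0, sum2 = 0.0;
  for (int i = 0; i < n; ++i) { sum += y[rows[i]]; sum2 += y[rows[i]] * y[rows[i]]; }
  const double mean = sum / n;
  const double sse = sum2 - sum * mean;
  nodes[node_id].value = mean;
  nodes[node_id].feature = -1;
  nodes[node_id].left = nodes[node_id].right = -1;

  if (n < 2 * min_node || depth >= max_depth || sse <= 1e-12) return;

  const int p = X.ncol();
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int n_try = (mtry > 0 && mtry < p) ? mtry : p;
  if (n_try < p) { // partial Fisher-Yates with R's RNG
    for (int j = 0; j < n_try; ++j) {
      int k = j + (int)std::floor(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(feats[j], feats[k]);
    }
  }

  double best_sse = sse - 1e-10;
  int best_feat = -1;
  double best_thr = 0.0;

  std::vector<int> ord(n);
  std::vector<double> xv(n), yv(n);
  for (int t = 0; t < n_try; ++t) {
    const int j = feats[t];
    for (int i = 0; i < n; ++i) { xv[i] = X(rows[i], j); ord[i] = i; }
    std::sort(ord.begin(), ord.end(),
              [&xv](int a, int b) { return xv[a] < xv[b]; });
    double ls = 0.0, ls2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      const double yi = y[rows[ord[i]]];
      ls += yi; ls2 += yi * yi;
      const int nl = i + 1, nr = n - nl;
      if (nl < min_node) continue;
      if (nr < min_node) break;
      const double xl = xv[ord[i]], xr = xv[ord[i + 1]];
      if (xr <= xl) continue; // no admissible threshold between ties
      const double rs = sum - ls, rs2 = sum2 - ls2;
      const double s = (ls2 - ls * ls / nl) + (rs2 - rs * rs / nr);
      if (s < best_sse) {
        best_sse = s;
        best_feat = j;
        best_thr = xl + (xr - xl) / 2.0;
      }
    }
  }

  if (best_feat < 0) return;

  std::vector<int> lrows, rrows;
  lrows.reserve(n); rrows.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (X(rows[i], best_feat) <= best_thr) lrows.push_back(rows[i]);
    else rrows.push_back(rows[i]);
  }
  if ((int)lrows.size() < min_node || (int)rrows.size() < min_node) return;

  const int li = nodes.size(); nodes.push_back(Node());
  const int ri = nodes.size(); nodes.push_back(Node());
  nodes[node_id].feature = best_feat;
  nodes[node_id].threshold = best_thr;
  nodes[node_id].left = li;
  nodes[node_id].right = ri;
  grow(X, y, lrows, depth + 1, min_node, max_depth, mtry, nodes, li);
  grow(X, y, rrows, depth + 1, min_node, max_depth, mtry, nodes, ri);
}

// [[Rcpp::export]]
List cpp_grow_tree(NumericMatrix X, NumericVector y, IntegerVector rows,
                   int min_node, int max_depth, int mtry) {
  if (rows.size() < 1) stop("empty row set");
  std::vector<int> rr(rows.begin(), rows.end()); // 0-based from R side
  std::vector<Node> nodes;
  nodes.push_back(Node());
  grow(X, y, rr, 0, min_node, max_depth, mtry, nodes, 0);
  const int m = nodes.size();
  IntegerVector feature(m), left(m), right(m);
  NumericVector threshold(m), value(m);
  for (int i = 0; i < m; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    value[i] = nodes[i].value;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["left"] = left, _["right"] = right, _["value"] = value);
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"], right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] = value[node];
  }
  return out;
}
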