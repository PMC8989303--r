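// Gradient-boosted decision trees for binary classification with
// logistic loss. Exact greedy split search (no subsampling), so fits are
// fully deterministic; second-order leaf values as in standard boosting:
//   leaf = -sum(g) / (sum(h) + lambda),  g = p - y,  h = p (1 - p).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct TreeNodes {
  // columns: feature (-1 for leaf), threshold, left, right, value
  std::vector<int> feature, left, right;
  std::vector<double> threshold, value;
  int add() {
    feature.push_back(-1); left.push_back(-1); right.push_back(-1);
    threshold.push_back(0.0); value.push_back(0.0);
    return (int)feature.size() - 1;
  }
};

void grow(const NumericMatrix& X, const std::vector<double>& g,
          const std::vector<double>& h, std::vector<int>& idx,
          int lo, int hi, int depth, int max_depth, double lambda,
          double min_child_weight, TreeNodes& t, int node) {
  double G = 0.0, H = 0.0;
  for (int i = lo; i < hi; ++i) { G += g[idx[i]]; H += h[idx[i]]; }
  double leaf_val = -G / (H + lambda);
  t.value[node] = leaf_val;
  if (depth >= max_depth || hi - lo < 2) return;

  const double parent_score = G * G / (H + lambda);
  double best_gain = 1e-12;
  int best_feat = -1;
  double best_thr = 0.0;

  int n = hi - lo;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  for (int j = 0; j < X.ncol(); ++j) {
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      double xa = X(a, j), xb = X(b, j);
      if (xa != xb) return xa < xb;
      return a < b;  // stable, deterministic
    });
    double GL = 0.0, HL = 0.0;
    for (int r = 0; r + 1 < n; ++r) {
      GL += g[ord[r]]; HL += h[ord[r]];
      double xcur = X(ord[r], j), xnext = X(ord[r + 1], j);
      if (xcur == xnext) continue;
      double HR = H - HL;
      if (HL < min_child_weight || HR < min_child_weight) continue;
      double GR = G - GL;
      double gain = GL * GL / (HL + lambda) + GR * GR / (HR + lambda)
                    - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_feat = j;
        best_thr = 0.5 * (xcur + xnext);
      }
    }
  }
  if (best_feat < 0) return;

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_feat) <= best_thr) ++mid;
  std::stable_partition(idx.begin() + lo, idx.begin() + hi,
                        [&](int a) { return X(a, best_feat) <= best_thr; });

  int lnode = t.add(), rnode = t.add();
  t.feature[node] = best_feat;
  t.threshold[node] = best_thr;
  t.left[node] = lnode;
  t.right[node] = rnode;
  grow(X, g, h, idx, lo, mid, depth + 1, max_depth, lambda,
       min_child_weight, t, lnode);
  grow(X, g, h, idx, mid, hi, depth + 1, max_depth, lambda,
       min_child_weight, t, rnode);
}

double tree_predict_one(const NumericMatrix& nodes, const NumericMatrix& X,
                        int row) {
  int cur = 0;
  while ((int)nodes(cur, 0) >= 0) {
    int f = (int)nodes(cur, 0);
    cur = (X(row, f) <= nodes(cur, 1)) ? (int)nodes(cur, 2)
                                       : (int)nodes(cur, 3);
  }
  return nodes(cur, 4);
}

NumericMatrix pack(const TreeNodes& t) {
  int n = (int)t.feature.size();
  NumericMatrix m(n, 5);
  for (int i = 0; i < n; ++i) {
    m(i, 0) = t.feature[i];
    m(i, 1) = t.threshold[i];
    m(i, 2) = t.left[i];
    m(i, 3) = t.right[i];
    m(i, 4) = t.value[i];
  }
  return m;
}

}  // namespace

// [[Rcpp::export]]
List gbt_fit_cpp(NumericMatrix X, NumericVector y, int n_trees,
                 double learning_rate, int max_depth, double lambda,
                 double min_child_weight) {
  int n = X.nrow();
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  ybar = std::min(std::max(ybar, 1e-6), 1.0 - 1e-6);
  double f0 = std::log(ybar / (1.0 - ybar));

  std::vector<double> F(n, f0), g(n), h(n);
  List trees(n_trees);
  for (int tr = 0; tr < n_trees; ++tr) {
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-F[i]));
      g[i] = p - y[i];
      h[i] = std::max(p * (1.0 - p), 1e-12);
    }
    TreeNodes t;
    int root = t.add();
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    grow(X, g, h, idx, 0, n, 0, max_depth, lambda, min_child_weight, t, root);
    NumericMatrix nodes = pack(t);
    for (int i = 0; i < n; ++i)
      F[i] += learning_rate * tree_predict_one(nodes, X, i);
    trees[tr] = nodes;
  }
  return List::create(_["f0"] = f0, _["trees"] = trees,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export]]
NumericVector gbt_predict_cpp(List model, NumericMatrix X) {
  double f0 = as<double>(model["f0"]);
  double lr = as<double>(model["learning_rate"]);
  List trees = model["trees"];
  int n = X.nrow();
  NumericVector out(n);
  std::vector<double> F(n, f0);
  for (int tr = 0; tr < trees.size(); ++tr) {
    NumericMatrix nodes = trees[tr];
    for (int i = 0; i < n; ++i)
      F[i] += lr * tree_predict_one(nodes, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] = 1.0 / (1.0 + std::exp(-F[i]));
  return out;
}
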