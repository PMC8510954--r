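// Weighted CART regression trees (variance splitting), used as the base
// learner for random forest, AdaBoost and gradient boosting. For 0/1
// responses, variance reduction coincides with Gini gain, so the same tree
// serves classification (leaf value = weighted class-1 probability) and
// regression (leaf value = weighted mean residual).
//
// Feature subsampling and bootstrap draws use R's RNG so that R-side
// set.seed() governs reproducibility.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct Node {
  int feature;      // -1 for leaf
  double threshold; // go left if x <= threshold
  int left, right;
  double value;     // weighted mean of y in node
};

static void build_node(const NumericMatrix &X, const NumericVector &y,
                       const NumericVector &w, std::vector<int> &idx,
                       int depth, int max_depth, int min_leaf, int mtry,
                       std::vector<Node> &nodes) {
  int me = (int)nodes.size();
  nodes.push_back(Node());
  double sw = 0.0, swy = 0.0;
  for (int i : idx) { sw += w[i]; swy += w[i] * y[i]; }
  double mean = sw > 0 ? swy / sw : 0.0;
  nodes[me].feature = -1;
  nodes[me].value = mean;
  nodes[me].left = nodes[me].right = -1;
  nodes[me].threshold = 0.0;
  int n = (int)idx.size();
  if (depth >= max_depth || n < 2 * min_leaf) return;

  int p = X.ncol();
  // sample mtry features without replacement
  std::vector<int> feats(p);
  for (int j = 0; j < p; ++j) feats[j] = j;
  int ntry = std::min(mtry, p);
  for (int j = 0; j < ntry; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(feats[j], feats[k]);
  }

  double best_gain = 1e-12;
  int best_f = -1, best_pos = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx);
  std::vector<int> best_ord;
  double parent_score = sw > 0 ? swy * swy / sw : 0.0;

  for (int j = 0; j < ntry; ++j) {
    int f = feats[j];
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return X(a, f) < X(b, f);
    });
    double lw = 0.0, lwy = 0.0;
    for (int pos = 0; pos < n - 1; ++pos) {
      int i = ord[pos];
      lw += w[i]; lwy += w[i] * y[i];
      if (X(ord[pos + 1], f) <= X(ord[pos], f)) continue;  // tied values
      if (pos + 1 < min_leaf || n - pos - 1 < min_leaf) continue;
      double rw = sw - lw, rwy = swy - lwy;
      if (lw <= 0 || rw <= 0) continue;
      double gain = lwy * lwy / lw + rwy * rwy / rw - parent_score;
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_pos = pos;
        best_thr = 0.5 * (X(ord[pos], f) + X(ord[pos + 1], f));
        best_ord = ord;
      }
    }
  }
  if (best_f < 0) return;

  std::vector<int> lidx(best_ord.begin(), best_ord.begin() + best_pos + 1);
  std::vector<int> ridx(best_ord.begin() + best_pos + 1, best_ord.end());
  nodes[me].feature = best_f;
  nodes[me].threshold = best_thr;
  nodes[me].left = (int)nodes.size();
  build_node(X, y, w, lidx, depth + 1, max_depth, min_leaf, mtry, nodes);
  nodes[me].right = (int)nodes.size();
  build_node(X, y, w, ridx, depth + 1, max_depth, min_leaf, mtry, nodes);
}

static NumericMatrix pack(const std::vector<Node> &nodes) {
  NumericMatrix out((int)nodes.size(), 5);
  for (size_t i = 0; i < nodes.size(); ++i) {
    out(i, 0) = nodes[i].feature;
    out(i, 1) = nodes[i].threshold;
    out(i, 2) = nodes[i].left;
    out(i, 3) = nodes[i].right;
    out(i, 4) = nodes[i].value;
  }
  colnames(out) = CharacterVector::create("feature", "threshold", "left",
                                          "right", "value");
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_fit_tree(NumericMatrix X, NumericVector y, NumericVector w,
                           int max_depth, int min_leaf, int mtry) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < X.nrow(); ++i) idx[i] = i;
  std::vector<Node> nodes;
  nodes.reserve(64);
  build_node(X, y, w, idx, 0, max_depth, min_leaf, mtry, nodes);
  return pack(nodes);
}

static int descend(const NumericMatrix &tree, const NumericMatrix &X, int i) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = X(i, f) <= tree(node, 1) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return node;
}

// [[Rcpp::export]]
NumericVector cpp_predict_tree(NumericMatrix tree, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = tree(descend(tree, X, i), 4);
  return out;
}

// leaf index per row (for per-leaf Newton updates in gradient boosting)
// [[Rcpp::export]]
IntegerVector cpp_tree_apply(NumericMatrix tree, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = descend(tree, X, i);
  return out;
}

// [[Rcpp::export]]
List cpp_fit_forest(NumericMatrix X, NumericVector y, int ntree, int mtry,
                    int max_depth, int min_leaf, double sample_frac) {
  int n = X.nrow();
  int m = std::max(1, (int)std::lround(sample_frac * n));
  List forest(ntree);
  NumericVector w(n);
  for (int t = 0; t < ntree; ++t) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int b = 0; b < m; ++b) {
      int k = (int)(unif_rand() * n);
      if (k >= n) k = n - 1;
      w[k] += 1.0;
    }
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) if (w[i] > 0) idx.push_back(i);
    std::vector<Node> nodes;
    nodes.reserve(64);
    build_node(X, y, w, idx, 0, max_depth, min_leaf, mtry, nodes);
    forest[t] = pack(nodes);
  }
  return forest;
}

// [[Rcpp::export]]
NumericVector cpp_predict_forest(List forest, NumericMatrix X) {
  int n = X.nrow();
  NumericVector out(n, 0.0);
  for (int t = 0; t < forest.size(); ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) out[i] += tree(descend(tree, X, i), 4);
  }
  for (int i = 0; i < n; ++i) out[i] /= forest.size();
  return out;
}

// discrete AdaBoost with shallow trees fitted on weighted 0/1 labels
// [[Rcpp::export]]
List cpp_fit_adaboost(NumericMatrix X, NumericVector y, int M, int depth,
                      int mtry) {
  int n = X.nrow();
  NumericVector w(n, 1.0 / n);
  std::vector<double> ypm(n);
  for (int i = 0; i < n; ++i) ypm[i] = 2.0 * y[i] - 1.0;
  List trees(M);
  NumericVector alphas(M);
  int used = 0;
  for (int m = 0; m < M; ++m) {
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; ++i) idx.push_back(i);
    std::vector<Node> nodes;
    nodes.reserve(16);
    build_node(X, y, w, idx, 0, depth, 1, mtry, nodes);
    NumericMatrix tr = pack(nodes);
    double err = 0.0;
    std::vector<double> pred(n);
    for (int i = 0; i < n; ++i) {
      pred[i] = tr(descend(tr, X, i), 4) >= 0.5 ? 1.0 : -1.0;
      if (pred[i] != ypm[i]) err += w[i];
    }
    if (err <= 1e-12) {
      trees[used] = tr;
      alphas[used] = 10.0;
      ++used;
      break;
    }
    if (err >= 0.5) break;
    double a = 0.5 * std::log((1.0 - err) / err);
    trees[used] = tr;
    alphas[used] = a;
    ++used;
    double sw = 0.0;
    for (int i = 0; i < n; ++i) {
      w[i] *= std::exp(-a * ypm[i] * pred[i]);
      sw += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= sw;
  }
  List out_trees(used);
  NumericVector out_alphas(used);
  for (int m = 0; m < used; ++m) { out_trees[m] = trees[m]; out_alphas[m] = alphas[m]; }
  return List::create(Named("trees") = out_trees, Named("alphas") = out_alphas);
}

// gradient boosting with logistic loss and per-leaf Newton steps
// [[Rcpp::export]]
List cpp_fit_gbm(NumericMatrix X, NumericVector y, int M, int depth,
                 double nu, int mtry) {
  int n = X.nrow();
  double pbar = 0.0;
  for (int i = 0; i < n; ++i) pbar += y[i];
  pbar /= n;
  double F0 = std::log(pbar / (1.0 - pbar));
  std::vector<double> F(n, F0);
  NumericVector ones(n, 1.0);
  NumericVector r(n);
  List trees(M);
  std::vector<int> idx0(n);
  for (int i = 0; i < n; ++i) idx0[i] = i;
  for (int m = 0; m < M; ++m) {
    std::vector<double> prob(n), h(n);
    for (int i = 0; i < n; ++i) {
      double z = F[i] > 30 ? 30 : (F[i] < -30 ? -30 : F[i]);
      prob[i] = 1.0 / (1.0 + std::exp(-z));
      r[i] = y[i] - prob[i];
      h[i] = std::max(prob[i] * (1.0 - prob[i]), 1e-6);
    }
    std::vector<int> idx(idx0);
    std::vector<Node> nodes;
    nodes.reserve(32);
    build_node(X, r, ones, idx, 0, depth, 3, mtry, nodes);
    NumericMatrix tr = pack(nodes);
    // per-leaf Newton step: sum(residual) / sum(hessian)
    int nn = tr.nrow();
    std::vector<double> num(nn, 0.0), den(nn, 0.0);
    std::vector<int> leaf(n);
    for (int i = 0; i < n; ++i) {
      leaf[i] = descend(tr, X, i);
      num[leaf[i]] += r[i];
      den[leaf[i]] += h[i];
    }
    for (int j = 0; j < nn; ++j)
      if ((int)tr(j, 0) == -1 && den[j] > 0) tr(j, 4) = num[j] / den[j];
    for (int i = 0; i < n; ++i) F[i] += nu * tr(leaf[i], 4);
    trees[m] = tr;
  }
  return List::create(Named("trees") = trees, Named("F0") = F0);
}
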