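// CART regression trees with bagging (random forest) and least-squares
// gradient boosting. Deterministic given R's RNG state: the only random
// draws are bootstrap indices and per-node feature subsets, both taken from
// R::unif_rand so that set.seed() in R fixes the whole fit.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // child node ids, -1 for leaf
  std::vector<double> value;     // node mean
};

struct SplitResult {
  int feature = -1;
  double threshold = 0.0;
  double gain = 0.0;             // SSE reduction, > 0 when valid
};

static SplitResult best_split(const NumericMatrix& X, const NumericVector& y,
                              const std::vector<int>& idx,
                              const std::vector<int>& features,
                              int min_leaf) {
  const int m = (int)idx.size();
  SplitResult best;
  double sum = 0.0;
  for (int i = 0; i < m; ++i) sum += y[idx[i]];
  const double parent_score = sum * sum / m;

  std::vector<std::pair<double, double> > xy(m);
  for (size_t fi = 0; fi < features.size(); ++fi) {
    const int j = features[fi];
    for (int i = 0; i < m; ++i) xy[i] = std::make_pair(X(idx[i], j), y[idx[i]]);
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    double sum_left = 0.0;
    for (int i = 1; i < m; ++i) {
      sum_left += xy[i - 1].second;
      if (xy[i].first == xy[i - 1].first) continue;
      if (i < min_leaf || (m - i) < min_leaf) continue;
      const double sum_right = sum - sum_left;
      const double gain =
          sum_left * sum_left / i + sum_right * sum_right / (m - i) - parent_score;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.feature = j;
        best.threshold = (xy[i - 1].first + xy[i].first) / 2.0;
      }
    }
  }
  return best;
}

static int grow(const NumericMatrix& X, const NumericVector& y,
                std::vector<int>& idx, int depth, int max_depth,
                int min_split, int min_leaf, int mtry,
                TreeNodes& tree, std::vector<double>& importance) {
  const int m = (int)idx.size();
  double sum = 0.0;
  for (int i = 0; i < m; ++i) sum += y[idx[i]];
  const double mean = sum / m;

  const int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.value.push_back(mean);

  if (depth >= max_depth || m < min_split || m < 2 * min_leaf) return node;

  const int p = X.ncol();
  std::vector<int> features;
  if (mtry >= p) {
    features.resize(p);
    for (int j = 0; j < p; ++j) features[j] = j;
  } else {
    // partial Fisher-Yates draw of mtry distinct features
    std::vector<int> pool(p);
    for (int j = 0; j < p; ++j) pool[j] = j;
    for (int k = 0; k < mtry; ++k) {
      int r = k + (int)(unif_rand() * (p - k));
      if (r >= p) r = p - 1;
      std::swap(pool[k], pool[r]);
      features.push_back(pool[k]);
    }
    std::sort(features.begin(), features.end());
  }

  SplitResult sp = best_split(X, y, idx, features, min_leaf);
  if (sp.feature < 0 || sp.gain <= 0.0) return node;

  importance[sp.feature] += sp.gain;

  std::vector<int> left_idx, right_idx;
  left_idx.reserve(m);
  right_idx.reserve(m);
  for (int i = 0; i < m; ++i) {
    if (X(idx[i], sp.feature) <= sp.threshold) left_idx.push_back(idx[i]);
    else right_idx.push_back(idx[i]);
  }
  if (left_idx.empty() || right_idx.empty()) return node;

  tree.feature[node] = sp.feature;
  tree.threshold[node] = sp.threshold;
  tree.left[node] = grow(X, y, left_idx, depth + 1, max_depth, min_split,
                         min_leaf, mtry, tree, importance);
  tree.right[node] = grow(X, y, right_idx, depth + 1, max_depth, min_split,
                          min_leaf, mtry, tree, importance);
  return node;
}

static List tree_to_list(const TreeNodes& t) {
  return List::create(
      _["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
      _["threshold"] = NumericVector(t.threshold.begin(), t.threshold.end()),
      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
      _["value"] = NumericVector(t.value.begin(), t.value.end()));
}

// accumulate scale * tree(x_i) into out for every row of X
static void tree_predict_acc(const List& tree, const NumericMatrix& X,
                             NumericVector& out, double scale) {
  IntegerVector feature = tree["feature"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"];
  IntegerVector right = tree["right"];
  NumericVector value = tree["value"];
  const int n = X.nrow();
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] >= 0) {
      node = (X(i, feature[node]) <= threshold[node]) ? left[node] : right[node];
    }
    out[i] += scale * value[node];
  }
}

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, NumericVector y, int n_trees, int max_depth,
            int min_split, int min_leaf, int mtry) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry <= 0 || mtry > p) mtry = p;
  RNGScope scope;
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int r = (int)(unif_rand() * n);
      if (r >= n) r = n - 1;
      idx[i] = r;
    }
    TreeNodes t;
    grow(X, y, idx, 0, max_depth, min_split, min_leaf, mtry, t, importance);
    trees[b] = tree_to_list(t);
  }
  double total = 0.0;
  for (int j = 0; j < p; ++j) total += importance[j];
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = total > 0 ? importance[j] / total : 0.0;
  return List::create(_["family"] = "random_forest", _["trees"] = trees,
                      _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n);
  for (int b = 0; b < B; ++b) tree_predict_acc(trees[b], X, out, 1.0);
  for (int i = 0; i < n; ++i) out[i] /= B;
  return out;
}

// [[Rcpp::export(name = ".gb_fit")]]
List gb_fit(NumericMatrix X, NumericVector y, int n_trees, double learning_rate,
            int max_depth, int min_split, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  double init = 0.0;
  for (int i = 0; i < n; ++i) init += y[i];
  init /= n;

  NumericVector resid(n);
  NumericVector fit(n, init);
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int b = 0; b < n_trees; ++b) {
    for (int i = 0; i < n; ++i) resid[i] = y[i] - fit[i];
    TreeNodes t;
    std::vector<int> node_idx = idx;
    grow(X, resid, node_idx, 0, max_depth, min_split, min_leaf, p, t, importance);
    List tl = tree_to_list(t);
    trees[b] = tl;
    tree_predict_acc(tl, X, fit, learning_rate);
  }
  double total = 0.0;
  for (int j = 0; j < p; ++j) total += importance[j];
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = total > 0 ? importance[j] / total : 0.0;
  return List::create(_["family"] = "gradient_boosting", _["trees"] = trees,
                      _["importance"] = imp, _["init"] = init,
                      _["learning_rate"] = learning_rate);
}

// [[Rcpp::export(name = ".gb_predict")]]
NumericVector gb_predict(List model, NumericMatrix X) {
  List trees = model["trees"];
  const double lr = as<double>(model["learning_rate"]);
  const double init = as<double>(model["init"]);
  const int n = X.nrow(), B = trees.size();
  NumericVector out(n, init);
  for (int b = 0; b < B; ++b) tree_predict_acc(trees[b], X, out, lr);
  return out;
}
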