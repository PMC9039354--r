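// Random forest for binary classification: CART trees on the gini criterion,
// bootstrap resampling and per-node feature subsampling (mtry). All draws use
// R's RNG so forests are reproducible under set.seed(). Impurity importance
// (weighted gini decrease, summed over nodes, averaged over trees) is
// accumulated for recursive feature elimination.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Tree {
  std::vector<int> feature;   // -1 for leaf
  std::vector<double> thr;
  std::vector<int> left, right;
  std::vector<double> prob;   // leaf: fraction of class 1
};

inline double gini(double n1, double n) {
  if (n <= 0.0) return 0.0;
  double p1 = n1 / n;
  return 2.0 * p1 * (1.0 - p1);
}

// draw m distinct feature indices from 0..p-1 (partial Fisher-Yates, R RNG)
void sample_features(std::vector<int> &pool, int m, std::vector<int> &out) {
  int p = pool.size();
  for (int i = 0; i < m; ++i) {
    int j = i + (int)(unif_rand() * (p - i));
    if (j >= p) j = p - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y;
  int mtry, max_depth, min_split;
  Tree tree;
  std::vector<double> importance;
  std::vector<int> pool;

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int mtry_,
          int max_depth_, int min_split_)
      : X(X_), y(y_), mtry(mtry_), max_depth(max_depth_), min_split(min_split_),
        importance(X_.ncol(), 0.0), pool(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) pool[j] = j;
  }

  int make_leaf(double n1, double n) {
    tree.feature.push_back(-1);
    tree.thr.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.prob.push_back(n > 0 ? n1 / n : 0.5);
    return tree.feature.size() - 1;
  }

  int build(std::vector<int> &idx, int depth) {
    double n = idx.size(), n1 = 0.0;
    for (int i : idx) n1 += y[i];
    bool pure = (n1 == 0.0 || n1 == n);
    if (pure || (int)n < min_split || (max_depth > 0 && depth >= max_depth))
      return make_leaf(n1, n);

    double parent_g = gini(n1, n);
    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;

    std::vector<int> feats(mtry);
    sample_features(pool, mtry, feats);

    std::vector<std::pair<double, int>> vals(idx.size());
    for (int f : feats) {
      for (size_t i = 0; i < idx.size(); ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      double nl = 0.0, nl1 = 0.0;
      for (size_t i = 0; i + 1 < vals.size(); ++i) {
        nl += 1.0;
        nl1 += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        double nr = n - nl, nr1 = n1 - nl1;
        double gain = parent_g - (nl / n) * gini(nl1, nl) - (nr / n) * gini(nr1, nr);
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }
    if (best_f < 0) return make_leaf(n1, n);

    std::vector<int> li, ri;
    for (int i : idx)
      (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return make_leaf(n1, n);

    importance[best_f] += n * best_gain;

    int node = make_leaf(n1, n);  // placeholder, overwritten below
    tree.feature[node] = best_f;
    tree.thr[node] = best_thr;
    int l = build(li, depth + 1);
    int r = build(ri, depth + 1);
    tree.left[node] = l;
    tree.right[node] = r;
    return node;
  }
};

double predict_tree(const Tree &t, const NumericMatrix &X, int row) {
  int node = 0;
  while (t.feature[node] >= 0)
    node = (X(row, t.feature[node]) <= t.thr[node]) ? t.left[node] : t.right[node];
  return t.prob[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit")]]
List rf_fit(NumericMatrix X, IntegerVector y, int ntree, int mtry,
            int max_depth, int min_split) {
  int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  List trees(ntree);
  NumericVector imp(p);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = (int)(unif_rand() * n);
      idx[i] = (j >= n) ? n - 1 : j;
    }
    Builder b(X, y, mtry, max_depth, min_split);
    b.build(idx, 0);
    trees[t] = List::create(
        _["feature"] = wrap(b.tree.feature), _["thr"] = wrap(b.tree.thr),
        _["left"] = wrap(b.tree.left), _["right"] = wrap(b.tree.right),
        _["prob"] = wrap(b.tree.prob));
    for (int j = 0; j < p; ++j) imp[j] += b.importance[j] / ntree;
  }
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export(name = ".rf_predict")]]
NumericVector rf_predict(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  int ntree = trees.size(), n = X.nrow();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tl = trees[t];
    Tree tr;
    tr.feature = as<std::vector<int>>(tl["feature"]);
    tr.thr = as<std::vector<double>>(tl["thr"]);
    tr.left = as<std::vector<int>>(tl["left"]);
    tr.right = as<std::vector<int>>(tl["right"]);
    tr.prob = as<std::vector<double>>(tl["prob"]);
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tr, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
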