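#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Minimal classification random forest (gini splits, bootstrap rows,
// mtry features per split, nodes grown to purity or min size). Uses R's
// RNG so results are reproducible under set.seed().

namespace {

struct Tree {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;
  std::vector<double> leaf;      // class-1 fraction at leaf
};

int rand_int(int n) {  // 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

double gini_impurity(int n1, int n) {
  if (n == 0) return 0.0;
  double p = (double)n1 / n;
  return 2.0 * p * (1.0 - p);
}

void grow(Tree &tree, const NumericMatrix &X, const IntegerVector &y,
          std::vector<int> &idx, int lo, int hi, int mtry, int min_node,
          double *imp, std::vector<int> &feat_pool) {
  const int n = hi - lo;
  int n1 = 0;
  for (int i = lo; i < hi; ++i) n1 += y[idx[i]];
  const int node = tree.feature.size();
  tree.feature.push_back(-1);
  tree.threshold.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.leaf.push_back(n == 0 ? 0.5 : (double)n1 / n);
  if (n < 2 * 1 || n <= min_node || n1 == 0 || n1 == n) return;

  const int p = X.ncol();
  // sample mtry distinct features
  for (int i = 0; i < p; ++i) feat_pool[i] = i;
  double parent = gini_impurity(n1, n);
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int> > vals(n);
  for (int m = 0; m < mtry; ++m) {
    int j = m + rand_int(p - m);
    std::swap(feat_pool[m], feat_pool[j]);
    const int f = feat_pool[m];
    for (int i = 0; i < n; ++i) {
      const int r = idx[lo + i];
      vals[i] = std::make_pair(X(r, f), y[r]);
    }
    std::sort(vals.begin(), vals.end());
    int l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      l1 += vals[i].second;
      if (vals[i].first == vals[i + 1].first) continue;
      const int nl = i + 1, nr = n - nl;
      double g = parent - ((double)nl / n) * gini_impurity(l1, nl)
                        - ((double)nr / n) * gini_impurity(n1 - l1, nr);
      if (g > best_gain) {
        best_gain = g;
        best_f = f;
        best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
      }
    }
  }
  if (best_f < 0) return;

  // partition idx[lo..hi) in place
  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return;  // degenerate; keep leaf

  imp[best_f] += best_gain * n;
  tree.feature[node] = best_f;
  tree.threshold[node] = best_thr;
  tree.left[node] = tree.feature.size();
  grow(tree, X, y, idx, lo, mid, mtry, min_node, imp, feat_pool);
  tree.right[node] = tree.feature.size();
  grow(tree, X, y, idx, mid, hi, mtry, min_node, imp, feat_pool);
}

}  // namespace

// [[Rcpp::export]]
List cpp_forest_fit(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                    int min_node) {
  const int n = X.nrow(), p = X.ncol();
  GetRNGstate();
  List trees(n_trees);
  std::vector<double> importance(p, 0.0);
  std::vector<int> idx(n), feat_pool(p);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < n; ++i) idx[i] = rand_int(n);  // bootstrap
    Tree tree;
    grow(tree, X, y, idx, 0, n, mtry, min_node, importance.data(), feat_pool);
    trees[t] = List::create(
        _["feature"] = wrap(tree.feature), _["threshold"] = wrap(tree.threshold),
        _["left"] = wrap(tree.left), _["right"] = wrap(tree.right),
        _["leaf"] = wrap(tree.leaf));
  }
  PutRNGstate();
  NumericVector imp(importance.begin(), importance.end());
  return List::create(_["trees"] = trees, _["importance"] = imp);
}

// [[Rcpp::export]]
NumericVector cpp_forest_predict(List forest, NumericMatrix X) {
  List trees = forest["trees"];
  const int n = X.nrow(), T = trees.size();
  NumericVector out(n);
  for (int t = 0; t < T; ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"];
    NumericVector leaf = tr["leaf"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = X(i, feature[node]) <= threshold[node] ? left[node] : right[node];
      out[i] += leaf[node];
    }
  }
  return out / (double)T;
}
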