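#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Binary-classification random forest: CART trees, Gini impurity, bootstrap
// resampling per tree, mtry features per node, grown to purity (min_node 1).
// All randomness is drawn from R's RNG so results are reproducible from
// set.seed() on the R side.

namespace {

struct TreeNode {
  int feat;      // -1 for a leaf
  double thr;    // x[feat] <= thr goes left
  int left, right;
  double pred;   // class-1 fraction in the leaf
};

int rand_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// Gini-best split for one feature over the node's samples.
// Returns impurity decrease (negative when no valid split exists).
bool best_split_feature(const NumericMatrix& X, const IntegerVector& y,
                        const std::vector<int>& idx, int f,
                        double& best_gain, double& best_thr) {
  const int n = (int)idx.size();
  std::vector<std::pair<double, int> > v(n);
  for (int i = 0; i < n; ++i) v[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
  std::sort(v.begin(), v.end());
  if (v.front().first == v.back().first) return false;

  int total1 = 0;
  for (int i = 0; i < n; ++i) total1 += v[i].second;
  double parent = 1.0 - (double)total1 * total1 / ((double)n * n)
                      - (double)(n - total1) * (n - total1) / ((double)n * n);
  int left1 = 0;
  bool found = false;
  for (int i = 0; i < n - 1; ++i) {
    left1 += v[i].second;
    if (v[i].first == v[i + 1].first) continue;
    int nl = i + 1, nr = n - nl;
    int right1 = total1 - left1;
    double gl = 1.0 - (double)left1 * left1 / ((double)nl * nl)
                    - (double)(nl - left1) * (nl - left1) / ((double)nl * nl);
    double gr = 1.0 - (double)right1 * right1 / ((double)nr * nr)
                    - (double)(nr - right1) * (nr - right1) / ((double)nr * nr);
    double gain = parent - ((double)nl / n) * gl - ((double)nr / n) * gr;
    if (!found || gain > best_gain) {
      best_gain = gain;
      best_thr = 0.5 * (v[i].first + v[i + 1].first);
      found = true;
    }
  }
  return found;
}

int build_node(const NumericMatrix& X, const IntegerVector& y,
               const std::vector<int>& idx, int mtry, int min_node,
               std::vector<TreeNode>& nodes, std::vector<int>& feat_pool) {
  const int n = (int)idx.size();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += y[idx[i]];

  TreeNode node;
  node.feat = -1; node.thr = 0.0; node.left = -1; node.right = -1;
  node.pred = (double)n1 / n;
  int me = (int)nodes.size();
  nodes.push_back(node);
  if (n1 == 0 || n1 == n || n < 2 * min_node || n < 2) return me;

  // sample mtry candidate features without replacement (partial Fisher-Yates)
  const int p = X.ncol();
  for (int i = 0; i < p; ++i) feat_pool[i] = i;
  double best_gain = 0.0, best_thr = 0.0;
  int best_feat = -1;
  for (int k = 0; k < mtry; ++k) {
    int j = k + rand_int(p - k);
    std::swap(feat_pool[k], feat_pool[j]);
    int f = feat_pool[k];
    double gain, thr;
    if (best_split_feature(X, y, idx, f, gain, thr) &&
        (best_feat < 0 || gain > best_gain)) {
      best_gain = gain; best_thr = thr; best_feat = f;
    }
  }
  if (best_feat < 0 || best_gain <= 0.0) return me;

  std::vector<int> li, ri;
  for (int i = 0; i < n; ++i) {
    if (X(idx[i], best_feat) <= best_thr) li.push_back(idx[i]);
    else ri.push_back(idx[i]);
  }
  if (li.empty() || ri.empty()) return me;

  nodes[me].feat = best_feat;
  nodes[me].thr = best_thr;
  int l = build_node(X, y, li, mtry, min_node, nodes, feat_pool);
  int r = build_node(X, y, ri, mtry, min_node, nodes, feat_pool);
  nodes[me].left = l;
  nodes[me].right = r;
  return me;
}

double tree_pred(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while ((int)tree(node, 0) >= 0) {
    int f = (int)tree(node, 0);
    node = (X(row, f) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                int min_node) {
  const int n = X.nrow();
  if (y.size() != n) stop("X and y disagree on the number of samples");
  if (mtry < 1 || mtry > X.ncol()) stop("mtry out of range");
  RNGScope scope;
  List forest(ntree);
  std::vector<int> feat_pool(X.ncol());
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> boot(n);
    for (int i = 0; i < n; ++i) boot[i] = rand_int(n);
    std::vector<TreeNode> nodes;
    build_node(X, y, boot, mtry, min_node, nodes, feat_pool);
    NumericMatrix tm((int)nodes.size(), 5);
    for (size_t i = 0; i < nodes.size(); ++i) {
      tm(i, 0) = nodes[i].feat;
      tm(i, 1) = nodes[i].thr;
      tm(i, 2) = nodes[i].left;
      tm(i, 3) = nodes[i].right;
      tm(i, 4) = nodes[i].pred;
    }
    forest[t] = tm;
  }
  return forest;
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericVector rf_predict_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int ntree = forest.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = forest[t];
    for (int i = 0; i < n; ++i) {
      // each tree casts a majority vote from its leaf
      out[i] += (tree_pred(tree, X, i) >= 0.5) ? 1.0 : 0.0;
    }
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
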