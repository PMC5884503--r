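// Regression random forest: CART trees with variance-reduction splits,
// bootstrap resampling, mtry candidate variables per node, impurity
// importance and out-of-bag predictions. Uses R's RNG so results are
// reproducible under set.seed()/withr::with_seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int var;        // split variable (0-based), -1 for leaf
  double split;   // threshold: x <= split goes left
  int left, right;
  double value;   // node mean (prediction for leaves)
};

// draw an integer uniformly in [0, n)
inline int runif_int(int n) {
  int k = (int)std::floor(unif_rand() * n);
  if (k >= n) k = n - 1; // unif_rand() can return values == 1 - eps
  return k;
}

class TreeGrower {
public:
  TreeGrower(const NumericMatrix& X, const NumericVector& y,
             int mtry, int min_node, std::vector<double>& importance)
    : X_(X), y_(y), mtry_(mtry), min_node_(min_node),
      imp_(importance), p_(X.ncol()) {}

  std::vector<Node> nodes;

  void grow(std::vector<int>& idx) {
    nodes.clear();
    build(idx, 0, (int)idx.size());
  }

private:
  const NumericMatrix& X_;
  const NumericVector& y_;
  int mtry_, min_node_;
  std::vector<double>& imp_;
  int p_;

  // Build node over idx[lo:hi); returns node index.
  int build(std::vector<int>& idx, int lo, int hi) {
    int n = hi - lo;
    double sum = 0.0, ss = 0.0;
    for (int i = lo; i < hi; ++i) { sum += y_[idx[i]]; }
    double mean = sum / n;
    for (int i = lo; i < hi; ++i) { double d = y_[idx[i]] - mean; ss += d * d; }

    int me = (int)nodes.size();
    nodes.push_back(Node{-1, 0.0, -1, -1, mean});
    if (n <= min_node_ || ss <= 1e-12) return me;

    // sample mtry distinct candidate variables (partial Fisher-Yates)
    std::vector<int> vars(p_);
    for (int j = 0; j < p_; ++j) vars[j] = j;
    int m = std::min(mtry_, p_);
    for (int j = 0; j < m; ++j) {
      int k = j + runif_int(p_ - j);
      std::swap(vars[j], vars[k]);
    }

    int best_var = -1;
    double best_gain = 0.0, best_split = 0.0;
    std::vector<std::pair<double,double> > xy(n);
    for (int jj = 0; jj < m; ++jj) {
      int v = vars[jj];
      for (int i = 0; i < n; ++i) {
        int r = idx[lo + i];
        xy[i] = std::make_pair(X_(r, v), y_[r]);
      }
      std::sort(xy.begin(), xy.end());
      if (xy[0].first == xy[n - 1].first) continue; // constant in node
      double lsum = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        lsum += xy[i].second;
        if (xy[i].first == xy[i + 1].first) continue;
        int nl = i + 1, nr = n - nl;
        double rsum = sum - lsum;
        // gain = SS_parent - (SS_L + SS_R); equivalent to the between-group term
        double gain = lsum * lsum / nl + rsum * rsum / nr - sum * sum / n;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_var = v;
          best_split = (xy[i].first + xy[i + 1].first) / 2.0;
        }
      }
    }
    if (best_var < 0) return me; // no valid split among candidates

    // partition idx[lo:hi) (stable, preserves order within sides)
    std::vector<int> lpart, rpart;
    lpart.reserve(n); rpart.reserve(n);
    for (int i = lo; i < hi; ++i) {
      if (X_(idx[i], best_var) <= best_split) lpart.push_back(idx[i]);
      else rpart.push_back(idx[i]);
    }
    std::copy(lpart.begin(), lpart.end(), idx.begin() + lo);
    std::copy(rpart.begin(), rpart.end(), idx.begin() + lo + (int)lpart.size());

    imp_[best_var] += best_gain;
    int mid = lo + (int)lpart.size();
    int l = build(idx, lo, mid);
    int r = build(idx, mid, hi);
    nodes[me].var = best_var;
    nodes[me].split = best_split;
    nodes[me].left = l;
    nodes[me].right = r;
    return me;
  }
};

NumericMatrix pack_tree(const std::vector<Node>& nodes) {
  NumericMatrix m((int)nodes.size(), 5);
  for (int i = 0; i < (int)nodes.size(); ++i) {
    m(i, 0) = nodes[i].var;
    m(i, 1) = nodes[i].split;
    m(i, 2) = nodes[i].left;
    m(i, 3) = nodes[i].right;
    m(i, 4) = nodes[i].value;
  }
  return m;
}

inline double predict_tree(const NumericMatrix& tree, const NumericMatrix& X, int row) {
  int node = 0;
  while (tree(node, 0) >= 0) {
    int v = (int)tree(node, 0);
    node = (X(row, v) <= tree(node, 1)) ? (int)tree(node, 2) : (int)tree(node, 3);
  }
  return tree(node, 4);
}

} // namespace

// [[Rcpp::export]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, int ntree, int mtry,
                     int min_node) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();
  std::vector<double> importance(p, 0.0);
  List trees(ntree);
  NumericVector oob_sum(n, 0.0);
  IntegerVector oob_count(n, 0);
  std::vector<int> inbag(n);
  std::vector<int> idx;
  TreeGrower grower(X, y, mtry, min_node, importance);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.resize(n);
    for (int i = 0; i < n; ++i) {
      int k = runif_int(n);
      idx[i] = k;
      inbag[k]++;
    }
    grower.grow(idx);
    NumericMatrix tree = pack_tree(grower.nodes);
    trees[t] = tree;
    for (int i = 0; i < n; ++i) {
      if (inbag[i] == 0) {
        oob_sum[i] += predict_tree(tree, X, i);
        oob_count[i]++;
      }
    }
  }

  NumericVector imp(p), oob(n);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / ntree;
  for (int i = 0; i < n; ++i)
    oob[i] = oob_count[i] > 0 ? oob_sum[i] / oob_count[i] : NA_REAL;
  return List::create(_["trees"] = trees, _["importance"] = imp,
                      _["oob_prediction"] = oob);
}

// [[Rcpp::export]]
NumericVector predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntree = trees.size();
  NumericVector out(n, 0.0);
  for (int t = 0; t < ntree; ++t) {
    NumericMatrix tree = trees[t];
    for (int i = 0; i < n; ++i) out[i] += predict_tree(tree, X, i);
  }
  for (int i = 0; i < n; ++i) out[i] /= ntree;
  return out;
}
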