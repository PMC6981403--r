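#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Gradient boosting of shallow regression trees for binary targets on binary
// (0/1 dummy) predictors, Bernoulli deviance with Newton leaf steps.
// Trees are stored flat: arrays indexed by node id; feature = -1 marks a leaf.
// All candidate features are binary, so a split is "x == 1 goes right".

namespace {

struct FlatTree {
  std::vector<int> feature;     // split feature (0-based), -1 for leaf
  std::vector<int> left, right; // child node ids, -1 for leaf
  std::vector<double> value;    // leaf value (log-odds increment); 0 internal
  std::vector<double> gain;     // SSE reduction at split; 0 for leaf
  std::vector<int> n;           // training samples reaching the node

  int new_node() {
    feature.push_back(-1);
    left.push_back(-1);
    right.push_back(-1);
    value.push_back(0.0);
    gain.push_back(0.0);
    n.push_back(0);
    return (int)feature.size() - 1;
  }
};

// Best single-feature split of `rows` by residual SSE reduction.
// gain(f) = (nL*nR/n) * (meanL - meanR)^2 over residuals; both children must
// hold >= min_leaf rows; ties broken by lowest feature index.
inline bool best_split_impl(const IntegerMatrix &X,
                            const std::vector<double> &resid,
                            const std::vector<int> &rows,
                            const std::vector<int> &feats, int min_leaf,
                            int &best_f, double &best_gain) {
  const int n = (int)rows.size();
  if (n < 2 * min_leaf) return false;
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += resid[rows[i]];
  best_f = -1;
  best_gain = 0.0;
  const int nrowX = X.nrow();
  for (size_t k = 0; k < feats.size(); ++k) {
    const int f = feats[k];
    const int *col = &X[(R_xlen_t)f * nrowX];
    double sumR = 0.0;
    int nR = 0;
    for (int i = 0; i < n; ++i) {
      const int r = rows[i];
      if (col[r] == 1) {
        sumR += resid[r];
        ++nR;
      }
    }
    const int nL = n - nR;
    if (nL < min_leaf || nR < min_leaf) continue;
    const double meanL = (tot - sumR) / nL, meanR = sumR / nR;
    const double d = meanL - meanR;
    const double g = ((double)nL * nR / n) * d * d;
    if (g > best_gain + 1e-15) { // strict improvement; earlier feature wins ties
      best_gain = g;
      best_f = f;
    }
  }
  return best_f >= 0 && best_gain > 0.0;
}

// Newton leaf value: sum(residual) / sum(p*(1-p)), guarded against empty hessian.
inline double leaf_newton(const std::vector<double> &resid,
                          const std::vector<double> &hess,
                          const std::vector<int> &rows) {
  double g = 0.0, h = 0.0;
  for (size_t i = 0; i < rows.size(); ++i) {
    g += resid[rows[i]];
    h += hess[rows[i]];
  }
  if (h < 1e-12) return 0.0;
  return g / h;
}

void grow(FlatTree &tree, int node, const IntegerMatrix &X,
          const std::vector<double> &resid, const std::vector<double> &hess,
          std::vector<int> &rows, const std::vector<int> &feats, int depth,
          int max_depth, int min_leaf, std::vector<double> &node_value_of_row,
          double *importance) {
  tree.n[node] = (int)rows.size();
  int f;
  double g;
  bool can = depth < max_depth &&
             best_split_impl(X, resid, rows, feats, min_leaf, f, g);
  if (!can) {
    const double v = leaf_newton(resid, hess, rows);
    tree.value[node] = v;
    for (size_t i = 0; i < rows.size(); ++i) node_value_of_row[rows[i]] = v;
    return;
  }
  tree.feature[node] = f;
  tree.gain[node] = g;
  importance[f] += g;
  std::vector<int> lrows, rrows;
  lrows.reserve(rows.size());
  rrows.reserve(rows.size());
  const int *col = &X[(R_xlen_t)f * X.nrow()];
  for (size_t i = 0; i < rows.size(); ++i) {
    if (col[rows[i]] == 1)
      rrows.push_back(rows[i]);
    else
      lrows.push_back(rows[i]);
  }
  rows.clear();
  rows.shrink_to_fit();
  tree.left[node] = tree.new_node();
  tree.right[node] = tree.new_node();
  grow(tree, tree.left[node], X, resid, hess, lrows, feats, depth + 1,
       max_depth, min_leaf, node_value_of_row, importance);
  grow(tree, tree.right[node], X, resid, hess, rrows, feats, depth + 1,
       max_depth, min_leaf, node_value_of_row, importance);
}

inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

List tree_to_list(const FlatTree &t) {
  return List::create(_["feature"] = IntegerVector(t.feature.begin(), t.feature.end()),
                      _["left"] = IntegerVector(t.left.begin(), t.left.end()),
                      _["right"] = IntegerVector(t.right.begin(), t.right.end()),
                      _["value"] = NumericVector(t.value.begin(), t.value.end()),
                      _["gain"] = NumericVector(t.gain.begin(), t.gain.end()),
                      _["n"] = IntegerVector(t.n.begin(), t.n.end()));
}

} // namespace

// [[Rcpp::export]]
List gbm_fit_cpp(IntegerMatrix X, NumericVector y, IntegerVector features,
                 int n_trees, int max_depth, double learn_rate, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X rows must match length of y");
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  if (ybar <= 0.0 || ybar >= 1.0) stop("degenerate target");
  const double base = std::log(ybar / (1.0 - ybar));

  std::vector<int> feats(features.begin(), features.end());
  std::vector<double> F(n, base), resid(n), hess(n), node_value(n);
  NumericVector importance(p);
  NumericVector losses(n_trees);
  List trees(n_trees);
  int built = 0;
  for (int t = 0; t < n_trees; ++t) {
    double absres = 0.0;
    for (int i = 0; i < n; ++i) {
      const double pi = sigmoid(F[i]);
      resid[i] = y[i] - pi;
      hess[i] = pi * (1.0 - pi);
      absres += std::fabs(resid[i]);
    }
    if (absres < 1e-10 * n) break; // target fully fitted: stop boosting early
    FlatTree tree;
    int root = tree.new_node();
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) rows[i] = i;
    std::fill(node_value.begin(), node_value.end(), 0.0);
    grow(tree, root, X, resid, hess, rows, feats, 0, max_depth, min_leaf,
         node_value, REAL(importance));
    double loss = 0.0;
    for (int i = 0; i < n; ++i) {
      F[i] += learn_rate * node_value[i];
      const double pi = sigmoid(F[i]);
      // Bernoulli deviance, clamped away from 0/1 for finiteness
      const double pc = std::min(std::max(pi, 1e-15), 1.0 - 1e-15);
      loss -= y[i] * std::log(pc) + (1.0 - y[i]) * std::log(1.0 - pc);
    }
    trees[t] = tree_to_list(tree);
    losses[t] = loss;
    ++built;
  }
  if (built < n_trees) {
    trees = trees[Range(0, std::max(built - 1, 0))];
    losses = losses[Range(0, std::max(built - 1, 0))];
    if (built == 0) {
      trees = List(0);
      losses = NumericVector(0);
    }
  }
  return List::create(_["base_score"] = base, _["trees"] = trees,
                      _["importance"] = importance, _["train_loss"] = losses);
}

// [[Rcpp::export]]
NumericVector gbm_predict_cpp(List trees, double base_score, double learn_rate,
                              IntegerMatrix X) {
  const int n = X.nrow();
  NumericVector F(n, base_score);
  for (int t = 0; t < trees.size(); ++t) {
    List tr = trees[t];
    IntegerVector feature = tr["feature"], left = tr["left"],
                  right = tr["right"];
    NumericVector value = tr["value"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0) {
        const int f = feature[node];
        node = (X(i, f) == 1) ? right[node] : left[node];
      }
      F[i] += learn_rate * value[node];
    }
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sigmoid(F[i]);
  return out;
}

// [[Rcpp::export]]
List best_split_cpp(IntegerMatrix X, NumericVector residuals,
                    IntegerVector rows, IntegerVector features, int min_leaf) {
  std::vector<double> resid(residuals.begin(), residuals.end());
  std::vector<int> rws(rows.begin(), rows.end());
  std::vector<int> feats(features.begin(), features.end());
  int f;
  double g;
  if (!best_split_impl(X, resid, rws, feats, min_leaf, f, g))
    return List::create(_["feature"] = NA_INTEGER, _["gain"] = NA_REAL);
  return List::create(_["feature"] = f + 1, _["gain"] = g);
}
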