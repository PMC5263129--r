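// Random forest for two-class cell classification.
//
// Fully grown CART trees (nodesize 1) on bootstrap samples, Gini-impurity
// splitting with a random feature subset (mtry) considered at every node,
// out-of-bag voting, and mean-decrease-in-Gini importance accumulated over
// trees. Written in-package because no forest implementation ships with this
// R installation; conventions follow the classic randomForest package.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Node {
  int feature;    // -1 for leaf
  double thr;     // go left if x <= thr
  int left, right;
  int pred;       // leaf class (0/1)
};

inline double gini(int n0, int n1) {
  const double n = n0 + n1;
  if (n <= 0.0) return 0.0;
  const double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

class TreeGrower {
 public:
  TreeGrower(const NumericMatrix& X, const IntegerVector& y, int mtry,
             std::mt19937& rng, std::vector<double>& importance)
      : X_(X), y_(y), mtry_(mtry), rng_(rng), imp_(importance),
        p_(X.ncol()), feat_idx_(p_) {
    for (int j = 0; j < p_; ++j) feat_idx_[j] = j;
  }

  // samp: bootstrap sample row indices (with repetition); consumed in place.
  std::vector<Node> grow(std::vector<int>& samp) {
    nodes_.clear();
    build(samp, 0, static_cast<int>(samp.size()));
    return nodes_;
  }

 private:
  int build(std::vector<int>& samp, int lo, int hi) {
    const int me = static_cast<int>(nodes_.size());
    nodes_.push_back(Node{-1, 0.0, -1, -1, 0});

    int n0 = 0, n1 = 0;
    for (int i = lo; i < hi; ++i) (y_[samp[i]] == 0 ? n0 : n1)++;
    nodes_[me].pred = (n1 > n0) ? 1 : 0;
    if (n0 == 0 || n1 == 0 || hi - lo < 2) return me;

    const double g_parent = gini(n0, n1);
    const int n_node = hi - lo;

    // sample mtry features without replacement (partial Fisher-Yates)
    for (int j = 0; j < mtry_; ++j) {
      std::uniform_int_distribution<int> pick(j, p_ - 1);
      std::swap(feat_idx_[j], feat_idx_[pick(rng_)]);
    }

    int best_feat = -1;
    double best_thr = 0.0, best_dec = 1e-12;
    std::vector<std::pair<double, int>> vals;
    vals.reserve(n_node);

    for (int j = 0; j < mtry_; ++j) {
      const int f = feat_idx_[j];
      vals.clear();
      for (int i = lo; i < hi; ++i)
        vals.emplace_back(X_(samp[i], f), y_[samp[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;

      int l0 = 0, l1 = 0;
      for (int i = 0; i + 1 < n_node; ++i) {
        (vals[i].second == 0 ? l0 : l1)++;
        if (vals[i].first == vals[i + 1].first) continue;
        const int r0 = n0 - l0, r1 = n1 - l1;
        const double dec = n_node * g_parent -
                           (l0 + l1) * gini(l0, l1) - (r0 + r1) * gini(r0, r1);
        if (dec > best_dec) {
          best_dec = dec;
          best_feat = f;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_feat < 0) return me;  // no admissible split among sampled features

    imp_[best_feat] += best_dec;

    // partition samples in place: x <= thr to the left
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (X_(samp[i], best_feat) <= best_thr) std::swap(samp[i], samp[mid++]);

    nodes_[me].feature = best_feat;
    nodes_[me].thr = best_thr;
    const int l = build(samp, lo, mid);
    const int r = build(samp, mid, hi);
    nodes_[me].left = l;
    nodes_[me].right = r;
    return me;
  }

  const NumericMatrix& X_;
  const IntegerVector& y_;
  const int mtry_;
  std::mt19937& rng_;
  std::vector<double>& imp_;
  const int p_;
  std::vector<int> feat_idx_;
  std::vector<Node> nodes_;
};

inline int predict_one(const std::vector<Node>& tree, const NumericMatrix& X,
                       int row) {
  int i = 0;
  while (tree[i].feature >= 0)
    i = (X(row, tree[i].feature) <= tree[i].thr) ? tree[i].left : tree[i].right;
  return tree[i].pred;
}

}  // namespace

// Grow a forest and return OOB class votes plus Gini importance.
// y must be 0/1; importance is the impurity decrease summed over splits,
// averaged over trees (randomForest's MeanDecreaseGini convention).
// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y dimensions disagree");
  if (mtry < 1 || mtry > p) stop("mtry out of range");
  if (n_trees < 1) stop("n_trees must be positive");

  std::mt19937 rng(static_cast<std::uint32_t>(seed));
  std::uniform_int_distribution<int> draw(0, n - 1);

  IntegerMatrix votes(n, 2);
  std::vector<double> importance(p, 0.0);
  std::vector<int> samp(n);
  std::vector<char> inbag(n);

  TreeGrower grower(X, y, mtry, rng, importance);

  for (int t = 0; t < n_trees; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      samp[i] = draw(rng);
      inbag[samp[i]] = 1;
    }
    std::vector<Node> tree = grower.grow(samp);
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) votes(i, predict_one(tree, X, i))++;
  }

  NumericVector imp(p);
  for (int j = 0; j < p; ++j) imp[j] = importance[j] / n_trees;

  return List::create(Named("votes") = votes, Named("importance") = imp);
}
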