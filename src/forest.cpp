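// Random forest classifier for the driver-transcript ranking: 100 bagged
// CART trees (gini splits, every predictor considered at every split, one
// observation minimum leaf size) with out-of-bag permutation importance.
// Importance follows the convention "mean over trees of the per-tree
// increase in OOB error after permuting one feature, divided by its standard
// deviation across trees", so a fixed prominence threshold transfers across
// cohorts. All randomness comes from one mt19937 seeded by the caller.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <algorithm>
// [[Rcpp::depends(RcppArmadillo)]]

struct Node {
  int feature = -1;       // -1 marks a leaf
  double threshold = 0.0; // go left if x[feature] <= threshold
  int left = -1, right = -1;
  int pred = 0;           // leaf class (0-based)
};

struct Tree {
  std::vector<Node> nodes;

  int predict(const double* row, int /*p*/) const {
    int cur = 0;
    while (nodes[cur].feature >= 0) {
      cur = (row[nodes[cur].feature] <= nodes[cur].threshold)
                ? nodes[cur].left
                : nodes[cur].right;
    }
    return nodes[cur].pred;
  }
};

static double gini(const std::vector<int>& counts, int total) {
  if (total == 0) return 0.0;
  double g = 1.0;
  for (int c : counts) {
    double f = (double)c / total;
    g -= f * f;
  }
  return g;
}

// Recursively grow a node over sample indices `idx`.
static int grow(Tree& tree, const arma::mat& X, const std::vector<int>& y,
                int K, std::vector<int>& idx) {
  const int n = (int)idx.size();
  std::vector<int> counts(K, 0);
  for (int i : idx) counts[y[i]]++;
  int node_id = (int)tree.nodes.size();
  tree.nodes.push_back(Node());

  int majority = 0;
  for (int k = 1; k < K; ++k)
    if (counts[k] > counts[majority]) majority = k;
  tree.nodes[node_id].pred = majority;

  bool pure = false;
  for (int k = 0; k < K; ++k)
    if (counts[k] == n) pure = true;
  if (pure || n < 2) return node_id;

  const double parent_imp = gini(counts, n);
  const int p = (int)X.n_cols;
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;

  std::vector<std::pair<double, int>> vals(n);
  for (int f = 0; f < p; ++f) {
    for (int i = 0; i < n; ++i) vals[i] = {X(idx[i], f), y[idx[i]]};
    std::sort(vals.begin(), vals.end());
    std::vector<int> left_counts(K, 0);
    int nl = 0;
    for (int i = 0; i + 1 < n; ++i) {
      left_counts[vals[i].second]++;
      nl++;
      if (vals[i].first == vals[i + 1].first) continue;
      int nr = n - nl;
      std::vector<int> right_counts(K);
      for (int k = 0; k < K; ++k) right_counts[k] = counts[k] - left_counts[k];
      double gain = parent_imp - ((double)nl / n) * gini(left_counts, nl) -
                    ((double)nr / n) * gini(right_counts, nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  if (best_f < 0) return node_id; // no improving split (e.g. identical rows)

  std::vector<int> lidx, ridx;
  for (int i : idx) {
    if (X(i, best_f) <= best_thr)
      lidx.push_back(i);
    else
      ridx.push_back(i);
  }
  if (lidx.empty() || ridx.empty()) return node_id;

  tree.nodes[node_id].feature = best_f;
  tree.nodes[node_id].threshold = best_thr;
  int l = grow(tree, X, y, K, lidx);
  tree.nodes[node_id].left = l;
  int r = grow(tree, X, y, K, ridx);
  tree.nodes[node_id].right = r;
  return node_id;
}

// [[Rcpp::export(name = ".forest_importance_cpp")]]
Rcpp::List forest_importance_cpp(const arma::mat& X,
                                 const arma::ivec& labels, int n_trees,
                                 int seed) {
  const int n = (int)X.n_rows, p = (int)X.n_cols;
  const int K = labels.max(); // labels are 1..K
  std::vector<int> y(n);
  for (int i = 0; i < n; ++i) y[i] = labels(i) - 1;

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);

  arma::mat delta(n_trees, p, arma::fill::zeros); // per-tree OOB error increase
  arma::vec oob_err(n_trees, arma::fill::zeros);
  std::vector<double> row(p);

  for (int t = 0; t < n_trees; ++t) {
    std::vector<char> inbag(n, 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int j = pick(rng);
      idx[i] = j;
      inbag[j] = 1;
    }
    Tree tree;
    grow(tree, X, y, K, idx);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    int wrong = 0;
    for (int i : oob) {
      for (int f = 0; f < p; ++f) row[f] = X(i, f);
      if (tree.predict(row.data(), p) != y[i]) wrong++;
    }
    double base_err = (double)wrong / oob.size();
    oob_err(t) = base_err;

    for (int f = 0; f < p; ++f) {
      // permute feature f among the OOB samples
      std::vector<int> perm = oob;
      for (int i = (int)perm.size() - 1; i > 0; --i) {
        std::uniform_int_distribution<int> u(0, i);
        std::swap(perm[i], perm[u(rng)]);
      }
      int wrong_p = 0;
      for (size_t k = 0; k < oob.size(); ++k) {
        int i = oob[k];
        for (int g = 0; g < p; ++g) row[g] = X(i, g);
        row[f] = X(perm[k], f);
        if (tree.predict(row.data(), p) != y[i]) wrong_p++;
      }
      delta(t, f) = (double)wrong_p / oob.size() - base_err;
    }
  }

  arma::rowvec m = arma::mean(delta, 0);
  arma::rowvec s = arma::stddev(delta, 0, 0); // normalized by n_trees - 1
  arma::rowvec importance(p);
  for (int f = 0; f < p; ++f)
    importance(f) = (s(f) > 0) ? m(f) / s(f) : 0.0;

  return Rcpp::List::create(
      Rcpp::Named("importance") = arma::vec(importance.t()),
      Rcpp::Named("mean_delta") = arma::vec(m.t()),
      Rcpp::Named("oob_error") = oob_err);
}
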