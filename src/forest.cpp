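// CART-style classification trees and a bagged random forest.
//
// Binary classification only (labels 0/1). Trees are grown on Gini impurity
// with a random candidate feature subset drawn independently at every split
// (classic random-forest behaviour: bootstrap resampling + per-split random
// feature selection + majority vote). Uses R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <stack>
#include <vector>

using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feat;     // split feature (0-based), -1 for leaf
  std::vector<double> thr;   // split threshold (go left if x <= thr)
  std::vector<int> left, right;
  std::vector<double> prob;  // fraction of positives in the node
};

int irand(int n) {
  int v;
  do {
    v = static_cast<int>(unif_rand() * n);
  } while (v >= n);
  return v;
}

// Partial Fisher-Yates: first `m` entries of a shuffled 0..p-1.
void sample_features(std::vector<int>& pool, int m) {
  const int p = static_cast<int>(pool.size());
  for (int i = 0; i < m; ++i) {
    int j = i + irand(p - i);
    std::swap(pool[i], pool[j]);
  }
}

struct Job {
  std::vector<int> rows;
  int slot;   // index into tree arrays to fill
  int depth;
};

int new_node(TreeBuf& t) {
  t.feat.push_back(-1);
  t.thr.push_back(0.0);
  t.left.push_back(-1);
  t.right.push_back(-1);
  t.prob.push_back(0.0);
  return static_cast<int>(t.feat.size()) - 1;
}

void grow_tree(const NumericMatrix& X, const IntegerVector& y,
               const std::vector<int>& boot_rows, int mtry, int min_node,
               int max_depth, TreeBuf& tree) {
  const int p = X.ncol();
  std::vector<int> pool(p);
  for (int j = 0; j < p; ++j) pool[j] = j;

  std::stack<Job> work;
  {
    Job root;
    root.rows = boot_rows;
    root.slot = new_node(tree);
    root.depth = 0;
    work.push(root);
  }
  std::vector<std::pair<double, int> > vals;

  while (!work.empty()) {
    Job job = work.top();
    work.pop();
    const std::vector<int>& rows = job.rows;
    const int n = static_cast<int>(rows.size());
    int npos = 0;
    for (int i = 0; i < n; ++i) npos += y[rows[i]];
    tree.prob[job.slot] = static_cast<double>(npos) / n;

    bool pure = (npos == 0 || npos == n);
    if (pure || n < 2 * min_node || (max_depth > 0 && job.depth >= max_depth)) {
      continue;  // leaf
    }

    sample_features(pool, mtry);
    double best_score = -1.0;  // weighted child Gini to minimize
    int best_feat = -1;
    double best_thr = 0.0;
    const double parent_gini =
        2.0 * (static_cast<double>(npos) / n) * (1.0 - static_cast<double>(npos) / n);

    for (int t = 0; t < mtry; ++t) {
      const int j = pool[t];
      vals.clear();
      for (int i = 0; i < n; ++i) {
        vals.push_back(std::make_pair(X(rows[i], j), y[rows[i]]));
      }
      std::sort(vals.begin(), vals.end());
      int pl = 0;
      for (int i = 0; i < n - 1; ++i) {
        pl += vals[i].second;
        if (vals[i].first == vals[i + 1].first) continue;
        const int nl = i + 1;
        const int nr = n - nl;
        if (nl < min_node || nr < min_node) continue;
        const int pr = npos - pl;
        const double gl = 2.0 * (static_cast<double>(pl) / nl) *
                          (1.0 - static_cast<double>(pl) / nl);
        const double gr = 2.0 * (static_cast<double>(pr) / nr) *
                          (1.0 - static_cast<double>(pr) / nr);
        const double score = (nl * gl + nr * gr) / n;
        if (best_feat < 0 || score < best_score - 1e-12) {
          best_score = score;
          best_feat = j;
          best_thr = 0.5 * (vals[i].first + vals[i + 1].first);
        }
      }
    }

    if (best_feat < 0 || best_score >= parent_gini - 1e-12) {
      continue;  // no impurity decrease: leaf
    }

    Job lj, rj;
    lj.depth = rj.depth = job.depth + 1;
    for (int i = 0; i < n; ++i) {
      if (X(rows[i], best_feat) <= best_thr) {
        lj.rows.push_back(rows[i]);
      } else {
        rj.rows.push_back(rows[i]);
      }
    }
    if (lj.rows.empty() || rj.rows.empty()) continue;  // degenerate; leaf
    tree.feat[job.slot] = best_feat;
    tree.thr[job.slot] = best_thr;
    lj.slot = new_node(tree);
    rj.slot = new_node(tree);
    tree.left[job.slot] = lj.slot;
    tree.right[job.slot] = rj.slot;
    work.push(lj);
    work.push(rj);
  }
}

List tree_to_list(const TreeBuf& t) {
  return List::create(Named("feat") = wrap(t.feat), Named("thr") = wrap(t.thr),
                      Named("left") = wrap(t.left),
                      Named("right") = wrap(t.right),
                      Named("prob") = wrap(t.prob));
}

double tree_prob(const IntegerVector& feat, const NumericVector& thr,
                 const IntegerVector& left, const IntegerVector& right,
                 const NumericVector& prob, const NumericMatrix& X, int row) {
  int node = 0;
  while (feat[node] >= 0) {
    node = (X(row, feat[node]) <= thr[node]) ? left[node] : right[node];
  }
  return prob[node];
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(NumericMatrix X, IntegerVector y, int n_trees, int mtry,
                int min_node, int max_depth, bool bootstrap) {
  const int n = X.nrow();
  if (n < 1) stop("rf_fit_cpp: empty training set");
  if (mtry < 1 || mtry > X.ncol()) stop("rf_fit_cpp: invalid mtry");
  List forest(n_trees);
  for (int b = 0; b < n_trees; ++b) {
    std::vector<int> rows(n);
    if (bootstrap) {
      for (int i = 0; i < n; ++i) rows[i] = irand(n);
    } else {
      for (int i = 0; i < n; ++i) rows[i] = i;
    }
    TreeBuf tree;
    grow_tree(X, y, rows, mtry, min_node, max_depth, tree);
    forest[b] = tree_to_list(tree);
  }
  return forest;
}

// Fraction of trees voting for the positive class (hard majority-vote
// aggregation: each tree votes with its leaf's majority class; leaf ties
// count as a negative vote).
// [[Rcpp::export(name = ".rf_vote_cpp")]]
NumericVector rf_vote_cpp(List forest, NumericMatrix X) {
  const int n = X.nrow();
  const int B = forest.size();
  NumericVector votes(n);
  for (int b = 0; b < B; ++b) {
    List t = forest[b];
    IntegerVector feat = t["feat"];
    NumericVector thr = t["thr"];
    IntegerVector left = t["left"];
    IntegerVector right = t["right"];
    NumericVector prob = t["prob"];
    for (int i = 0; i < n; ++i) {
      if (tree_prob(feat, thr, left, right, prob, X, i) > 0.5) votes[i] += 1.0;
    }
  }
  for (int i = 0; i < n; ++i) votes[i] /= B;
  return votes;
}
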