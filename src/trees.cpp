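// CART trees with exact greedy splits, bagged into a random forest or boosted
// into multiclass softmax gradient-boosted trees. Self-contained because the
// target environment ships no tree-learning package. Determinism: all
// randomness flows from one std::mt19937 seeded by the caller; ties in split
// search resolve to the first candidate in (feature, threshold) scan order.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
#include <random>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int feat = -1;          // -1 => leaf
  double thr = 0.0;
  int left = -1, right = -1;
  std::vector<double> val; // class distribution (RF) or scalar value (GBT)
};

struct SplitResult {
  int feat = -1;
  double thr = 0.0;
  double score = -std::numeric_limits<double>::infinity();
};

typedef std::vector<Node> Tree;

// X column-major (n x F)
inline double xval(const NumericMatrix& X, int i, int f) { return X(i, f); }

// Classification split: maximize gini decrease == minimize weighted child gini.
SplitResult best_split_gini(const NumericMatrix& X, const IntegerVector& y, int K,
                            const std::vector<int>& idx,
                            const std::vector<int>& feats, int min_leaf) {
  SplitResult best;
  const int n = idx.size();
  std::vector<int> ord(n);
  std::vector<int> cntL(K), cntR(K);
  for (int f : feats) {
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return xval(X, idx[a], f) < xval(X, idx[b], f);
    });
    std::fill(cntL.begin(), cntL.end(), 0);
    std::fill(cntR.begin(), cntR.end(), 0);
    for (int i = 0; i < n; ++i) ++cntR[y[idx[i]]];
    int nL = 0, nR = n;
    for (int i = 0; i < n - 1; ++i) {
      int yi = y[idx[ord[i]]];
      ++cntL[yi]; --cntR[yi]; ++nL; --nR;
      double v1 = xval(X, idx[ord[i]], f), v2 = xval(X, idx[ord[i + 1]], f);
      if (v2 <= v1) continue;
      if (nL < min_leaf || nR < min_leaf) continue;
      double sL = 0, sR = 0;
      for (int k = 0; k < K; ++k) {
        sL += (double)cntL[k] * cntL[k];
        sR += (double)cntR[k] * cntR[k];
      }
      double score = sL / nL + sR / nR;  // == n - weighted gini impurity * n
      if (score > best.score) {
        best.score = score;
        best.feat = f;
        best.thr = 0.5 * (v1 + v2);
      }
    }
  }
  return best;
}

// Regression split on residuals: maximize sumL^2/nL + sumR^2/nR.
SplitResult best_split_sse(const NumericMatrix& X, const std::vector<double>& r,
                           const std::vector<int>& idx,
                           const std::vector<int>& feats, int min_leaf) {
  SplitResult best;
  const int n = idx.size();
  std::vector<int> ord(n);
  for (int f : feats) {
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
      return xval(X, idx[a], f) < xval(X, idx[b], f);
    });
    double sumT = 0;
    for (int i = 0; i < n; ++i) sumT += r[idx[i]];
    double sumL = 0;
    for (int i = 0; i < n - 1; ++i) {
      sumL += r[idx[ord[i]]];
      double v1 = xval(X, idx[ord[i]], f), v2 = xval(X, idx[ord[i + 1]], f);
      if (v2 <= v1) continue;
      int nL = i + 1, nR = n - nL;
      if (nL < min_leaf || nR < min_leaf) continue;
      double sumR = sumT - sumL;
      double score = sumL * sumL / nL + sumR * sumR / nR;
      if (score > best.score) {
        best.score = score;
        best.feat = f;
        best.thr = 0.5 * (v1 + v2);
      }
    }
  }
  return best;
}

std::vector<int> sample_feats(int F, int mtry, std::mt19937& rng) {
  std::vector<int> all(F);
  std::iota(all.begin(), all.end(), 0);
  if (mtry >= F) return all;
  // partial Fisher-Yates, then sort for deterministic scan order
  for (int i = 0; i < mtry; ++i) {
    std::uniform_int_distribution<int> d(i, F - 1);
    std::swap(all[i], all[d(rng)]);
  }
  std::vector<int> out(all.begin(), all.begin() + mtry);
  std::sort(out.begin(), out.end());
  return out;
}

void grow_class_tree(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
                     int K, std::vector<int>& idx, int depth, int max_depth,
                     int min_split, int mtry, std::mt19937& rng) {
  int me = tree.size();
  tree.push_back(Node());
  const int n = idx.size();
  std::vector<int> cnt(K, 0);
  for (int i : idx) ++cnt[y[i]];
  int nz = 0;
  for (int k = 0; k < K; ++k) if (cnt[k]) ++nz;
  bool leaf = (depth >= max_depth) || (n < min_split) || (nz <= 1);
  SplitResult sp;
  if (!leaf) {
    sp = best_split_gini(X, y, K, idx, sample_feats(X.ncol(), mtry, rng), 1);
    if (sp.feat < 0) leaf = true;
  }
  if (leaf) {
    tree[me].val.resize(K);
    for (int k = 0; k < K; ++k) tree[me].val[k] = (double)cnt[k] / n;
    return;
  }
  std::vector<int> li, ri;
  for (int i : idx)
    (xval(X, i, sp.feat) <= sp.thr ? li : ri).push_back(i);
  tree[me].feat = sp.feat;
  tree[me].thr = sp.thr;
  tree[me].left = tree.size();
  grow_class_tree(tree, X, y, K, li, depth + 1, max_depth, min_split, mtry, rng);
  tree[me].right = tree.size();
  grow_class_tree(tree, X, y, K, ri, depth + 1, max_depth, min_split, mtry, rng);
}

void grow_reg_tree(Tree& tree, const NumericMatrix& X, const std::vector<double>& r,
                   const std::vector<double>& h, std::vector<int>& idx, int depth,
                   int max_depth, int min_split, std::mt19937& rng) {
  int me = tree.size();
  tree.push_back(Node());
  const int n = idx.size();
  bool leaf = (depth >= max_depth) || (n < min_split);
  SplitResult sp;
  std::vector<int> feats(X.ncol());
  std::iota(feats.begin(), feats.end(), 0);
  if (!leaf) {
    sp = best_split_sse(X, r, idx, feats, 1);
    if (sp.feat < 0) leaf = true;
  }
  if (leaf) {
    // Newton leaf value for multiclass softmax boosting
    double sr = 0, sh = 0;
    for (int i : idx) { sr += r[i]; sh += h[i]; }
    tree[me].val.assign(1, sh > 1e-12 ? sr / sh : 0.0);
    return;
  }
  std::vector<int> li, ri;
  for (int i : idx)
    (xval(X, i, sp.feat) <= sp.thr ? li : ri).push_back(i);
  tree[me].feat = sp.feat;
  tree[me].thr = sp.thr;
  tree[me].left = tree.size();
  grow_reg_tree(tree, X, r, h, li, depth + 1, max_depth, min_split, rng);
  tree[me].right = tree.size();
  grow_reg_tree(tree, X, r, h, ri, depth + 1, max_depth, min_split, rng);
}

// serialize a tree into a numeric matrix: rows = nodes,
// cols = feat, thr, left, right, val... (val padded to vlen)
NumericMatrix pack_tree(const Tree& tree, int vlen) {
  NumericMatrix m(tree.size(), 4 + vlen);
  for (size_t i = 0; i < tree.size(); ++i) {
    m(i, 0) = tree[i].feat;
    m(i, 1) = tree[i].thr;
    m(i, 2) = tree[i].left;
    m(i, 3) = tree[i].right;
    for (int j = 0; j < vlen; ++j)
      m(i, 4 + j) = (size_t)j < tree[i].val.size() ? tree[i].val[j] : 0.0;
  }
  return m;
}

// returns the leaf row index; values live in columns 4..(4+vlen-1)
inline int leaf_of(const NumericMatrix& m, const NumericMatrix& X, int i) {
  int node = 0;
  while (m(node, 0) >= 0)
    node = X(i, (int)m(node, 0)) <= m(node, 1) ? (int)m(node, 2) : (int)m(node, 3);
  return node;
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(const NumericMatrix& X, const IntegerVector& y, int K,
                int n_trees, int mtry, int max_depth, int min_split, int seed) {
  const int n = X.nrow();
  std::mt19937 rng(seed);
  List trees(n_trees);
  for (int t = 0; t < n_trees; ++t) {
    std::vector<int> idx(n);
    std::uniform_int_distribution<int> d(0, n - 1);
    for (int i = 0; i < n; ++i) idx[i] = d(rng);
    std::sort(idx.begin(), idx.end());
    Tree tree;
    grow_class_tree(tree, X, y, K, idx, 0, max_depth, min_split, mtry, rng);
    trees[t] = pack_tree(tree, K);
  }
  return trees;
}

// [[Rcpp::export]]
NumericMatrix cpp_rf_predict(const List& trees, const NumericMatrix& X, int K) {
  const int n = X.nrow();
  NumericMatrix P(n, K);
  for (int t = 0; t < trees.size(); ++t) {
    NumericMatrix m = trees[t];
    for (int i = 0; i < n; ++i) {
      int leaf = leaf_of(m, X, i);
      for (int k = 0; k < K; ++k) P(i, k) += m(leaf, 4 + k);
    }
  }
  const double nt = trees.size();
  for (int i = 0; i < n * K; ++i) P[i] /= nt;
  return P;
}

// [[Rcpp::export]]
List cpp_gbt_fit(const NumericMatrix& X, const IntegerVector& y, int K,
                 int n_rounds, int max_depth, double learning_rate,
                 int min_split, int seed) {
  const int n = X.nrow();
  std::mt19937 rng(seed);
  std::vector<double> score(n * K, 0.0);
  std::vector<double> p(n * K), r(n), h(n);
  List out(n_rounds * K);
  const double kfac = (double)(K - 1) / K;
  for (int round = 0; round < n_rounds; ++round) {
    // softmax
    for (int i = 0; i < n; ++i) {
      double mx = score[i];
      for (int k = 1; k < K; ++k) mx = std::max(mx, score[i + k * n]);
      double s = 0;
      for (int k = 0; k < K; ++k) {
        p[i + k * n] = std::exp(score[i + k * n] - mx);
        s += p[i + k * n];
      }
      for (int k = 0; k < K; ++k) p[i + k * n] /= s;
    }
    for (int k = 0; k < K; ++k) {
      for (int i = 0; i < n; ++i) {
        double pk = p[i + k * n];
        r[i] = kfac * (((y[i] == k) ? 1.0 : 0.0) - pk);
        h[i] = kfac * pk * (1.0 - pk);
        if (h[i] < 1e-12) h[i] = 1e-12;
      }
      std::vector<int> idx(n);
      std::iota(idx.begin(), idx.end(), 0);
      Tree tree;
      grow_reg_tree(tree, X, r, h, idx, 0, max_depth, min_split, rng);
      NumericMatrix m = pack_tree(tree, 1);
      out[round * K + k] = m;
      for (int i = 0; i < n; ++i)
        score[i + k * n] += learning_rate * m(leaf_of(m, X, i), 4);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gbt_predict(const List& trees, const NumericMatrix& X, int K,
                              double learning_rate) {
  const int n = X.nrow();
  const int n_rounds = trees.size() / K;
  std::vector<double> score(n * K, 0.0);
  for (int round = 0; round < n_rounds; ++round)
    for (int k = 0; k < K; ++k) {
      NumericMatrix m = trees[round * K + k];
      for (int i = 0; i < n; ++i)
        score[i + k * n] += learning_rate * m(leaf_of(m, X, i), 4);
    }
  NumericMatrix P(n, K);
  for (int i = 0; i < n; ++i) {
    double mx = score[i];
    for (int k = 1; k < K; ++k) mx = std::max(mx, score[i + k * n]);
    double s = 0;
    for (int k = 0; k < K; ++k) {
      P(i, k) = std::exp(score[i + k * n] - mx);
      s += P(i, k);
    }
    for (int k = 0; k < K; ++k) P(i, k) /= s;
  }
  return P;
}
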