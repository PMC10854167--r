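// Classification random forest with out-of-bag (OOB) error and OOB
// permutation importance (mean decrease in accuracy).
//
// Implemented here because the selection procedure retrains hundreds of
// small forests (forward inclusion over a ranked candidate list) and needs
// bit-reproducible results across platforms: all randomness comes from a
// std::mt19937 seeded from R, with hand-rolled bounded draws (library
// distributions are implementation-defined).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

// bounded draw in [0, m); small modulo bias is irrelevant here and keeps
// the stream identical on every platform
inline int draw(std::mt19937 &rng, int m) {
  return static_cast<int>(rng() % static_cast<uint32_t>(m));
}

struct Tree {
  std::vector<int> feature;      // split feature, -1 at leaves
  std::vector<double> threshold; // goes left when x <= threshold
  std::vector<int> left, right;  // child node ids, -1 at leaves
  std::vector<int> pred;         // majority class at the node (0-based)
};

// lowest class index wins ties: deterministic argmax
inline int arg_majority(const std::vector<int> &cnt) {
  int best = 0;
  for (size_t c = 1; c < cnt.size(); ++c)
    if (cnt[c] > cnt[best]) best = static_cast<int>(c);
  return best;
}

struct Builder {
  const NumericMatrix &X;
  const IntegerVector &y; // 0-based classes
  int nclass, mtry, node_size;
  std::mt19937 &rng;
  Tree tree;
  std::vector<int> feats; // permutation workspace for mtry sampling

  Builder(const NumericMatrix &X_, const IntegerVector &y_, int nclass_,
          int mtry_, int node_size_, std::mt19937 &rng_)
      : X(X_), y(y_), nclass(nclass_), mtry(mtry_), node_size(node_size_),
        rng(rng_), feats(X_.ncol()) {
    for (int j = 0; j < X_.ncol(); ++j) feats[j] = j;
  }

  int build(std::vector<int> &idx) {
    std::vector<int> cnt(nclass, 0);
    for (int i : idx) cnt[y[i]]++;

    int node = static_cast<int>(tree.feature.size());
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(arg_majority(cnt));

    int present = 0;
    for (int c : cnt)
      if (c > 0) present++;
    int n = static_cast<int>(idx.size());
    if (n <= node_size || present < 2) return node; // pure or minimal node

    // parent score: sum_c cnt_c^2 / n (maximising child scores minimises
    // the gini-weighted impurity)
    double parent_score = 0.0;
    for (int c : cnt) parent_score += static_cast<double>(c) * c;
    parent_score /= n;

    // draw mtry features without replacement (partial Fisher-Yates)
    int p = X.ncol();
    int m = std::min(mtry, p);
    for (int j = 0; j < m; ++j) {
      int k = j + draw(rng, p - j);
      std::swap(feats[j], feats[k]);
    }

    double best_score = parent_score + 1e-12;
    int best_f = -1;
    double best_t = 0.0;

    std::vector<std::pair<double, int>> vals(n);
    std::vector<int> lcnt(nclass), rcnt(nclass);
    for (int j = 0; j < m; ++j) {
      int f = feats[j];
      for (int i = 0; i < n; ++i)
        vals[i] = std::make_pair(X(idx[i], f), y[idx[i]]);
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue; // constant
      std::fill(lcnt.begin(), lcnt.end(), 0);
      rcnt = cnt;
      double lsum = 0.0, rsum = 0.0; // sum_c count_c^2 on each side
      for (int c : cnt) rsum += static_cast<double>(c) * c;
      for (int i = 0; i < n - 1; ++i) {
        int c = vals[i].second;
        lsum += 2.0 * lcnt[c] + 1.0; // (x+1)^2 - x^2
        rsum -= 2.0 * rcnt[c] - 1.0; // x^2 - (x-1)^2
        lcnt[c]++;
        rcnt[c]--;
        if (vals[i].first == vals[i + 1].first) continue;
        double score = lsum / (i + 1) + rsum / (n - i - 1);
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_t = vals[i].first + (vals[i + 1].first - vals[i].first) / 2.0;
          if (best_t <= vals[i].first) best_t = vals[i].first; // fp guard
        }
      }
    }

    if (best_f < 0) return node;

    std::vector<int> li, ri;
    li.reserve(n);
    ri.reserve(n);
    for (int i : idx)
      (X(i, best_f) <= best_t ? li : ri).push_back(i);
    if (li.empty() || ri.empty()) return node; // degenerate fp split

    tree.feature[node] = best_f;
    tree.threshold[node] = best_t;
    int L = build(li);
    int R = build(ri);
    tree.left[node] = L;
    tree.right[node] = R;
    return node;
  }
};

// predict one sample; when feature == swap_f its value is overridden
inline int predict_one(const Tree &t, const NumericMatrix &X, int i,
                       int swap_f = -1, double swap_val = 0.0) {
  int node = 0;
  while (t.feature[node] >= 0) {
    int f = t.feature[node];
    double x = (f == swap_f) ? swap_val : X(i, f);
    node = (x <= t.threshold[node]) ? t.left[node] : t.right[node];
  }
  return t.pred[node];
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_fit(NumericMatrix X, IntegerVector y, int nclass, int ntree,
                int mtry, int node_size, int seed, bool importance) {
  int n = X.nrow(), p = X.ncol();
  std::mt19937 rng(static_cast<uint32_t>(seed));

  IntegerMatrix oob_votes(n, nclass);
  std::vector<double> imp(p, 0.0);
  List trees(ntree);

  std::vector<int> idx(n), inbag(n), oob, oob_pred, perm;
  std::vector<bool> used(p);

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    for (int i = 0; i < n; ++i) {
      int s = draw(rng, n);
      idx[i] = s;
      inbag[s]++;
    }
    Builder b(X, y, nclass, mtry, node_size, rng);
    std::vector<int> root_idx(idx);
    b.build(root_idx);
    const Tree &tr = b.tree;

    oob.clear();
    for (int i = 0; i < n; ++i)
      if (inbag[i] == 0) oob.push_back(i);

    oob_pred.resize(oob.size());
    int nerr = 0;
    for (size_t u = 0; u < oob.size(); ++u) {
      int pr = predict_one(tr, X, oob[u]);
      oob_pred[u] = pr;
      oob_votes(oob[u], pr)++;
      if (pr != y[oob[u]]) nerr++;
    }

    if (importance && !oob.empty()) {
      double err0 = static_cast<double>(nerr) / oob.size();
      std::fill(used.begin(), used.end(), false);
      for (size_t k = 0; k < tr.feature.size(); ++k)
        if (tr.feature[k] >= 0) used[tr.feature[k]] = true;
      // one OOB permutation per feature per tree
      perm.resize(oob.size());
      for (int f = 0; f < p; ++f) {
        if (!used[f]) continue; // exact zero contribution
        for (size_t u = 0; u < perm.size(); ++u) perm[u] = oob[u];
        for (int u = static_cast<int>(perm.size()) - 1; u > 0; --u)
          std::swap(perm[u], perm[draw(rng, u + 1)]);
        int e = 0;
        for (size_t u = 0; u < oob.size(); ++u) {
          int pr = predict_one(tr, X, oob[u], f, X(perm[u], f));
          if (pr != y[oob[u]]) e++;
        }
        imp[f] += static_cast<double>(e) / oob.size() - err0;
      }
    }

    trees[t] = List::create(
        Named("feature") = IntegerVector(tr.feature.begin(), tr.feature.end()),
        Named("threshold") =
            NumericVector(tr.threshold.begin(), tr.threshold.end()),
        Named("left") = IntegerVector(tr.left.begin(), tr.left.end()),
        Named("right") = IntegerVector(tr.right.begin(), tr.right.end()),
        Named("pred") = IntegerVector(tr.pred.begin(), tr.pred.end()));
  }

  // overall OOB error: majority vote over trees where the sample was OOB
  int nv = 0, nerr = 0;
  IntegerVector oob_call(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int tot = 0, best = 0;
    for (int c = 0; c < nclass; ++c) {
      tot += oob_votes(i, c);
      if (oob_votes(i, c) > oob_votes(i, best)) best = c;
    }
    if (tot == 0) continue;
    nv++;
    oob_call[i] = best;
    if (best != y[i]) nerr++;
  }
  double oob_error = nv > 0 ? static_cast<double>(nerr) / nv : NA_REAL;

  NumericVector importance_out(p);
  for (int f = 0; f < p; ++f) importance_out[f] = imp[f] / ntree;

  return List::create(Named("trees") = trees,
                      Named("oob_votes") = oob_votes,
                      Named("oob_call") = oob_call,
                      Named("oob_error") = oob_error,
                      Named("importance") = importance_out);
}

// [[Rcpp::export]]
IntegerMatrix cpp_rf_votes(List trees, NumericMatrix X, int nclass) {
  int n = X.nrow();
  IntegerMatrix votes(n, nclass);
  for (int t = 0; t < trees.size(); ++t) {
    List tl = trees[t];
    Tree tr;
    IntegerVector feature = tl["feature"], left = tl["left"],
                  right = tl["right"], pred = tl["pred"];
    NumericVector threshold = tl["threshold"];
    tr.feature.assign(feature.begin(), feature.end());
    tr.threshold.assign(threshold.begin(), threshold.end());
    tr.left.assign(left.begin(), left.end());
    tr.right.assign(right.begin(), right.end());
    tr.pred.assign(pred.begin(), pred.end());
    if (tr.feature.empty() || tr.feature.size() != tr.pred.size())
      stop("malformed tree in forest");
    for (int i = 0; i < n; ++i) votes(i, predict_one(tr, X, i))++;
  }
  return votes;
}
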