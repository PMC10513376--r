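// Balanced random forest backend: Gini CART trees with per-split feature
// subsampling, using histogram split search on up to 256 per-feature
// quantile bins (thresholds are real feature values, so prediction runs on
// raw data). The balanced bootstrap is drawn in R (auditable inbag matrix)
// and passed in; this file only grows and queries trees. Own Mersenne
// Twister per tree so results are reproducible and independent of R's RNG
// state.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

constexpr int MAX_BINS = 256;

struct FlatTree {
  // node arrays; feature == -1 marks a leaf, pred then holds the class id
  std::vector<int> feature;
  std::vector<double> threshold;
  std::vector<int> left;
  std::vector<int> right;
  std::vector<int> pred;
};

struct NodeTask {
  int lo, hi;    // range within the master slot array
  int node_id;
  int depth;
};

// per-feature quantile cut points over the training column; code(x) is the
// number of cut points < x, so "code <= b" is exactly "x <= cuts[b]"
void make_cuts(const double* col, int n, std::vector<double>& cuts) {
  std::vector<double> v(col, col + n);
  std::sort(v.begin(), v.end());
  cuts.clear();
  for (int b = 1; b < MAX_BINS; ++b) {
    double q = v[(size_t)((double)b * n / MAX_BINS)];
    if (cuts.empty() || q > cuts.back()) cuts.push_back(q);
  }
  if (!cuts.empty() && cuts.back() >= v[n - 1]) cuts.pop_back();
}

FlatTree grow_tree(const std::vector<uint8_t>& cb, const std::vector<int>& yb,
                   const std::vector<std::vector<double>>& cuts, int s,
                   int p, int n_classes, int mtry, int min_node,
                   int max_depth, std::mt19937& rng) {
  FlatTree tree;
  std::vector<NodeTask> stack;
  std::vector<int> slots(s), buf(s);
  for (int i = 0; i < s; ++i) slots[i] = i;
  std::vector<int> feat_pool(p);
  std::vector<int> cnt_total(n_classes), cnt_left(n_classes);
  std::vector<int> hist((size_t)MAX_BINS * n_classes);

  auto new_node = [&tree]() {
    tree.feature.push_back(-1);
    tree.threshold.push_back(0.0);
    tree.left.push_back(-1);
    tree.right.push_back(-1);
    tree.pred.push_back(0);
    return (int)tree.feature.size() - 1;
  };

  stack.push_back({0, s, new_node(), 0});

  while (!stack.empty()) {
    NodeTask nd = stack.back();
    stack.pop_back();
    const int lo = nd.lo, hi = nd.hi, m = hi - lo;

    std::fill(cnt_total.begin(), cnt_total.end(), 0);
    for (int i = lo; i < hi; ++i) cnt_total[yb[slots[i]]]++;

    int maj = 0;
    for (int k = 1; k < n_classes; ++k)
      if (cnt_total[k] > cnt_total[maj]) maj = k;
    tree.pred[nd.node_id] = maj;

    bool pure = (cnt_total[maj] == m);
    if (pure || m < 2 * min_node ||
        (max_depth > 0 && nd.depth >= max_depth))
      continue;

    // random feature order; the first mtry features that admit a valid
    // split are the candidate set (features constant within the node do
    // not use up draws, so impure nodes keep splitting when possible)
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    for (int j = 0; j < p - 1; ++j) {
      std::uniform_int_distribution<int> pick(j, p - 1);
      std::swap(feat_pool[j], feat_pool[pick(rng)]);
    }

    double sq_tot = 0.0;
    for (int k = 0; k < n_classes; ++k)
      sq_tot += (double)cnt_total[k] * cnt_total[k];

    double best_score = -1.0;  // maximize sq_l/nl + sq_r/nr
    int best_feat = -1, best_bin = -1;
    int evaluated = 0;

    for (int c = 0; c < p && evaluated < std::min(mtry, p); ++c) {
      const int j = feat_pool[c];
      bool had_valid = false;
      const int n_bins = (int)cuts[j].size() + 1;
      if (n_bins < 2) continue;
      const uint8_t* codes = &cb[(size_t)j * s];
      std::fill(hist.begin(), hist.begin() + (size_t)n_bins * n_classes, 0);
      for (int i = lo; i < hi; ++i) {
        const int slot = slots[i];
        hist[(size_t)codes[slot] * n_classes + yb[slot]]++;
      }
      std::fill(cnt_left.begin(), cnt_left.end(), 0);
      double sq_l = 0.0, sq_r = sq_tot;
      int nl = 0;
      for (int b = 0; b < n_bins - 1; ++b) {
        const int* hb = &hist[(size_t)b * n_classes];
        for (int k = 0; k < n_classes; ++k) {
          const int c_k = hb[k];
          if (c_k == 0) continue;
          sq_l += (2.0 * cnt_left[k] + c_k) * c_k;
          const int cr = cnt_total[k] - cnt_left[k];
          sq_r -= (2.0 * cr - c_k) * c_k;
          cnt_left[k] += c_k;
          nl += c_k;
        }
        if (nl < min_node || nl == 0) continue;
        const int nr = m - nl;
        if (nr < min_node || nr == 0) break;
        const double score = sq_l / nl + sq_r / nr;
        had_valid = true;
        if (score > best_score) {
          best_score = score;
          best_feat = j;
          best_bin = b;
        }
      }
      if (had_valid) ++evaluated;
    }

    // require a real impurity decrease over the parent
    if (best_feat < 0 || best_score <= sq_tot / m + 1e-12) continue;

    const uint8_t* bcodes = &cb[(size_t)best_feat * s];
    int il = lo, ir = 0;
    for (int i = lo; i < hi; ++i) {
      const int slot = slots[i];
      if (bcodes[slot] <= best_bin) slots[il++] = slot;
      else buf[ir++] = slot;
    }
    std::copy(buf.begin(), buf.begin() + ir, slots.begin() + il);
    const int nl = il - lo;

    const int left_id = new_node();
    const int right_id = new_node();
    tree.feature[nd.node_id] = best_feat;
    tree.threshold[nd.node_id] = cuts[best_feat][best_bin];
    tree.left[nd.node_id] = left_id;
    tree.right[nd.node_id] = right_id;
    stack.push_back({lo, lo + nl, left_id, nd.depth + 1});
    stack.push_back({lo + nl, hi, right_id, nd.depth + 1});
  }
  return tree;
}

}  // namespace

// [[Rcpp::export(name = ".brf_grow")]]
List brf_grow(NumericMatrix X, IntegerVector y, IntegerMatrix inbag,
              int n_classes, int mtry, int min_node, int max_depth,
              int seed) {
  const int n = X.nrow(), p = X.ncol();
  const int s = inbag.nrow(), n_trees = inbag.ncol();
  if (p < 1) stop("at least one feature is required");

  // quantile cut points and 8-bit codes, once per forest
  std::vector<std::vector<double>> cuts(p);
  std::vector<uint8_t> codes((size_t)n * p);
  for (int j = 0; j < p; ++j) {
    const double* col = &X(0, j);
    make_cuts(col, n, cuts[j]);
    const std::vector<double>& q = cuts[j];
    for (int i = 0; i < n; ++i) {
      codes[(size_t)j * n + i] =
          (uint8_t)(std::lower_bound(q.begin(), q.end(), col[i]) -
                    q.begin());
    }
  }

  List forest(n_trees);
  std::vector<uint8_t> cb((size_t)s * p);
  std::vector<int> yb(s);
  for (int t = 0; t < n_trees; ++t) {
    for (int i = 0; i < s; ++i) {
      const int row = inbag(i, t) - 1;
      if (row < 0 || row >= n) stop("inbag index out of range");
      yb[i] = y[row];
      for (int j = 0; j < p; ++j)
        cb[(size_t)j * s + i] = codes[(size_t)j * n + row];
    }
    // decorrelated per-tree stream; golden-ratio increment avoids overlap
    std::mt19937 rng((uint32_t)seed + 0x9E3779B9u * (uint32_t)(t + 1));
    FlatTree tr = grow_tree(cb, yb, cuts, s, p, n_classes, mtry, min_node,
                            max_depth, rng);
    forest[t] = List::create(
        _["feature"] = IntegerVector(tr.feature.begin(), tr.feature.end()),
        _["threshold"] = NumericVector(tr.threshold.begin(),
                                       tr.threshold.end()),
        _["left"] = IntegerVector(tr.left.begin(), tr.left.end()),
        _["right"] = IntegerVector(tr.right.begin(), tr.right.end()),
        _["pred"] = IntegerVector(tr.pred.begin(), tr.pred.end()));
  }
  return forest;
}

// [[Rcpp::export(name = ".brf_votes")]]
IntegerMatrix brf_votes(List forest, NumericMatrix X, int n_classes) {
  const int n = X.nrow();
  const int n_trees = forest.size();
  IntegerMatrix votes(n, n_classes);
  for (int t = 0; t < n_trees; ++t) {
    List tr = forest[t];
    IntegerVector feature = tr["feature"];
    NumericVector threshold = tr["threshold"];
    IntegerVector left = tr["left"], right = tr["right"], pred = tr["pred"];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feature[node] >= 0)
        node = (X(i, feature[node]) <= threshold[node]) ? left[node]
                                                        : right[node];
      votes(i, pred[node])++;
    }
  }
  return votes;
}
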