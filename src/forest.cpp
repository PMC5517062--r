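// Random forest classifier: bagged CART trees, Gini impurity with sample
// weights, probabilistic (leaf class-distribution) voting, OOB estimates.
// Deterministic for a fixed seed.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  unsigned long long state;
  explicit Rng(unsigned long long seed) : state(seed * 6364136223846793005ULL + 1442695040888963407ULL) {}
  unsigned long long next() {
    state ^= state >> 12; state ^= state << 25; state ^= state >> 27;
    return state * 2685821657736338717ULL;
  }
  int below(int n) { return (int)(next() % (unsigned long long)n); }
};

struct Node {
  int feature = -1;        // -1: leaf
  double threshold = 0.0;
  int left = -1, right = -1;
  std::vector<double> dist; // leaf: weighted class distribution (sums to 1)
};

struct TreeBuilder {
  const NumericMatrix &X;
  const IntegerVector &y;
  const std::vector<double> &w; // per-sample weight (class weight * count in bag)
  int K, mtry;
  Rng &rng;
  std::vector<Node> nodes;

  TreeBuilder(const NumericMatrix &X, const IntegerVector &y,
              const std::vector<double> &w, int K, int mtry, Rng &rng)
    : X(X), y(y), w(w), K(K), mtry(mtry), rng(rng) {}

  int build(std::vector<int> &idx) {
    int id = (int)nodes.size();
    nodes.push_back(Node());
    std::vector<double> cls(K, 0.0);
    double total = 0.0;
    for (int i : idx) { cls[y[i]] += w[i]; total += w[i]; }
    bool pure = true;
    int first = y[idx[0]];
    for (int i : idx) if (y[i] != first) { pure = false; break; }
    if (pure || idx.size() < 2) { make_leaf(id, cls, total); return id; }

    // parent impurity term: sum of squared class weights
    double parent_ssq = 0.0;
    for (int k = 0; k < K; k++) parent_ssq += cls[k] * cls[k];

    int p = X.ncol();
    // sample mtry features without replacement (partial Fisher-Yates)
    std::vector<int> feats(p);
    for (int j = 0; j < p; j++) feats[j] = j;
    int m = std::min(mtry, p);
    for (int j = 0; j < m; j++) std::swap(feats[j], feats[j + rng.below(p - j)]);

    double best_gain = 0.0; int best_f = -1; double best_t = 0.0;
    std::vector<std::pair<double, int> > vals(idx.size());
    std::vector<double> lcls(K);
    for (int jj = 0; jj < m; jj++) {
      int f = feats[jj];
      for (size_t r = 0; r < idx.size(); r++) vals[r] = std::make_pair(X(idx[r], f), idx[r]);
      std::sort(vals.begin(), vals.end());
      std::fill(lcls.begin(), lcls.end(), 0.0);
      double lw = 0.0;
      for (size_t r = 0; r + 1 < vals.size(); r++) {
        int i = vals[r].second;
        lcls[y[i]] += w[i]; lw += w[i];
        if (vals[r].first == vals[r + 1].first) continue;
        double lssq = 0.0, rssq = 0.0;
        for (int k = 0; k < K; k++) {
          lssq += lcls[k] * lcls[k];
          double rc = cls[k] - lcls[k];
          rssq += rc * rc;
        }
        double rw = total - lw;
        // weighted Gini decrease (up to constants): ssq_l/w_l + ssq_r/w_r
        double gain = lssq / lw + rssq / rw - parent_ssq / total;
        if (gain > best_gain + 1e-12) {
          best_gain = gain; best_f = f;
          best_t = 0.5 * (vals[r].first + vals[r + 1].first);
        }
      }
    }
    if (best_f < 0) { make_leaf(id, cls, total); return id; }
    std::vector<int> li, ri;
    for (int i : idx) {
      if (X(i, best_f) <= best_t) li.push_back(i); else ri.push_back(i);
    }
    if (li.empty() || ri.empty()) { make_leaf(id, cls, total); return id; }
    nodes[id].feature = best_f;
    nodes[id].threshold = best_t;
    int l = build(li);
    int r = build(ri);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  void make_leaf(int id, const std::vector<double> &cls, double total) {
    nodes[id].dist.assign(cls.begin(), cls.end());
    if (total > 0) for (int k = 0; k < K; k++) nodes[id].dist[k] /= total;
  }

  const std::vector<double> &predict(const NumericMatrix &M, int row) const {
    int id = 0;
    while (nodes[id].feature >= 0) {
      id = (M(row, nodes[id].feature) <= nodes[id].threshold)
             ? nodes[id].left : nodes[id].right;
    }
    return nodes[id].dist;
  }
};

} // namespace

// [[Rcpp::export]]
List vm_rf_cpp(NumericMatrix X, IntegerVector y, NumericMatrix Xtest,
               int n_classes, int n_trees, int mtry,
               NumericVector class_weight, int seed) {
  const int n = X.nrow(), ntest = Xtest.nrow(), K = n_classes;
  if (n == 0) stop("empty training set");
  Rng rng(static_cast<unsigned long long>(seed) + 7ULL);

  NumericMatrix prob_test(std::max(ntest, 0), K);
  NumericMatrix oob_prob(n, K);
  IntegerVector oob_count(n);

  std::vector<double> w(n);
  std::vector<int> in_bag(n);
  for (int t = 0; t < n_trees; t++) {
    std::fill(in_bag.begin(), in_bag.end(), 0);
    for (int i = 0; i < n; i++) in_bag[rng.below(n)]++;
    std::vector<int> idx;
    idx.reserve(n);
    for (int i = 0; i < n; i++) {
      if (in_bag[i] > 0) {
        idx.push_back(i);
        w[i] = class_weight[y[i]] * in_bag[i];
      }
    }
    TreeBuilder tb(X, y, w, K, mtry, rng);
    tb.build(idx);
    for (int r = 0; r < ntest; r++) {
      const std::vector<double> &d = tb.predict(Xtest, r);
      for (int k = 0; k < K; k++) prob_test(r, k) += d[k];
    }
    for (int i = 0; i < n; i++) {
      if (in_bag[i] == 0) {
        const std::vector<double> &d = tb.predict(X, i);
        for (int k = 0; k < K; k++) oob_prob(i, k) += d[k];
        oob_count[i]++;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  for (int r = 0; r < ntest; r++)
    for (int k = 0; k < K; k++) prob_test(r, k) /= n_trees;
  for (int i = 0; i < n; i++) {
    if (oob_count[i] > 0)
      for (int k = 0; k < K; k++) oob_prob(i, k) /= oob_count[i];
  }
  return List::create(_["prob_test"] = prob_test, _["oob_prob"] = oob_prob,
                      _["oob_count"] = oob_count);
}
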