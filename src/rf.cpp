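// Two-class classification random forest: bootstrap CART trees with Gini
// splits, out-of-bag error, permutation importance (mean decrease in OOB
// accuracy) and optional prediction on held-out data. Self-contained RNG
// (splitmix64) so results are bit-reproducible across platforms and
// independent of R's RNG state.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

struct SplitRng {
  uint64_t s;
  explicit SplitRng(uint64_t seed) : s(seed + 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // small-n modulo bias is negligible for forest sampling
  int unif_int(int n) { return static_cast<int>(next() % (uint64_t)n); }
};

struct Tree {
  std::vector<int> feature;    // -1 for leaf
  std::vector<double> thresh;
  std::vector<int> left, right;
  std::vector<int> pred;       // leaf class, -1 otherwise
  std::vector<char> used;      // features appearing in any split

  int predict(const double* x, int stride) const {
    int node = 0;
    while (feature[node] >= 0)
      node = (x[(size_t)feature[node] * stride] <= thresh[node])
                 ? left[node] : right[node];
    return pred[node];
  }
};

double gini(int c1, int n) {
  if (n == 0) return 0.0;
  double p = (double)c1 / n;
  return 2.0 * p * (1.0 - p);
}

// Grow one node; idx holds sample indices for this node.
int grow(Tree& tree, const NumericMatrix& X, const IntegerVector& y,
         std::vector<int>& idx, int lo, int hi, SplitRng& rng, int mtry,
         std::vector<int>& feat_pool,
         std::vector<std::pair<double, int>>& buf) {
  const int m = hi - lo;
  int c1 = 0;
  for (int i = lo; i < hi; ++i) c1 += y[idx[i]];
  const int node = (int)tree.feature.size();
  tree.feature.push_back(-1);
  tree.thresh.push_back(0.0);
  tree.left.push_back(-1);
  tree.right.push_back(-1);
  tree.pred.push_back(c1 * 2 > m ? 1 : 0);  // vote tie -> class 0
  if (c1 == 0 || c1 == m || m < 2) return node;

  const double parent = gini(c1, m);
  const int p = X.ncol();
  double best_gain = 1e-12;
  int best_f = -1;
  double best_thr = 0.0;
  // sample mtry candidate features without replacement (partial Fisher-Yates)
  for (int k = 0; k < mtry; ++k) {
    int j = k + rng.unif_int(p - k);
    std::swap(feat_pool[k], feat_pool[j]);
    const int f = feat_pool[k];
    buf.clear();
    for (int i = lo; i < hi; ++i)
      buf.emplace_back(X(idx[i], f), y[idx[i]]);
    std::sort(buf.begin(), buf.end());
    int lc1 = 0;
    for (int i = 0; i < m - 1; ++i) {
      lc1 += buf[i].second;
      if (buf[i].first == buf[i + 1].first) continue;
      const int nl = i + 1, nr = m - nl;
      const double gain = parent
          - ((double)nl / m) * gini(lc1, nl)
          - ((double)nr / m) * gini(c1 - lc1, nr);
      if (gain > best_gain) {
        best_gain = gain;
        best_f = f;
        best_thr = buf[i].first + 0.5 * (buf[i + 1].first - buf[i].first);
      }
    }
  }
  if (best_f < 0) return node;  // no candidate feature separates the node

  int mid = lo;
  for (int i = lo; i < hi; ++i)
    if (X(idx[i], best_f) <= best_thr) std::swap(idx[i], idx[mid++]);
  if (mid == lo || mid == hi) return node;  // numeric guard

  tree.feature[node] = best_f;
  tree.thresh[node] = best_thr;
  tree.pred[node] = -1;
  tree.used[best_f] = 1;
  const int l = grow(tree, X, y, idx, lo, mid, rng, mtry, feat_pool, buf);
  tree.left[node] = l;
  const int r = grow(tree, X, y, idx, mid, hi, rng, mtry, feat_pool, buf);
  tree.right[node] = r;
  return node;
}

}  // namespace

// [[Rcpp::export(name = "cpp_random_forest")]]
List cpp_random_forest(NumericMatrix X, IntegerVector y, int ntree, int mtry,
                       double seed, Nullable<NumericMatrix> Xtest = R_NilValue,
                       bool importance = true) {
  const int n = X.nrow(), p = X.ncol();
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;
  SplitRng rng((uint64_t)seed);

  NumericMatrix Xt;
  int ntest = 0;
  if (Xtest.isNotNull()) {
    Xt = Xtest.get();
    ntest = Xt.nrow();
  }

  std::vector<int> oob_votes0(n, 0), oob_votes1(n, 0);
  std::vector<double> imp(p, 0.0);
  std::vector<double> test_votes(ntest, 0.0);
  std::vector<int> idx, inbag(n), oob;
  std::vector<int> feat_pool(p);
  std::vector<std::pair<double, int>> buf;
  std::vector<double> xrow(p);
  std::vector<int> perm;

  for (int t = 0; t < ntree; ++t) {
    std::fill(inbag.begin(), inbag.end(), 0);
    idx.clear();
    for (int i = 0; i < n; ++i) {
      int s = rng.unif_int(n);
      idx.push_back(s);
      inbag[s]++;
    }
    Tree tree;
    tree.used.assign(p, 0);
    for (int j = 0; j < p; ++j) feat_pool[j] = j;
    grow(tree, X, y, idx, 0, (int)idx.size(), rng, mtry, feat_pool, buf);

    oob.clear();
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);

    // OOB votes (row-major copy so predict() can stride by 1)
    int base_correct = 0;
    std::vector<int> oob_pred(oob.size());
    for (size_t k = 0; k < oob.size(); ++k) {
      const int i = oob[k];
      for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
      const int cls = tree.predict(xrow.data(), 1);
      oob_pred[k] = cls;
      if (cls == 1) oob_votes1[i]++; else oob_votes0[i]++;
      if (cls == y[i]) base_correct++;
    }

    if (importance && !oob.empty()) {
      const int no = (int)oob.size();
      perm.resize(no);
      for (int f = 0; f < p; ++f) {
        if (!tree.used[f]) continue;  // unused feature: zero decrease
        for (int k = 0; k < no; ++k) perm[k] = k;
        for (int k = no - 1; k > 0; --k)
          std::swap(perm[k], perm[rng.unif_int(k + 1)]);
        int correct = 0;
        for (int k = 0; k < no; ++k) {
          const int i = oob[k];
          for (int j = 0; j < p; ++j) xrow[j] = X(i, j);
          xrow[f] = X(oob[perm[k]], f);
          if (tree.predict(xrow.data(), 1) == y[i]) correct++;
        }
        imp[f] += (double)(base_correct - correct) / no;
      }
    }

    for (int i = 0; i < ntest; ++i) {
      for (int j = 0; j < p; ++j) xrow[j] = Xt(i, j);
      test_votes[i] += tree.predict(xrow.data(), 1);
    }
  }

  int n_oob = 0, wrong = 0;
  NumericVector oob_prob(n);
  for (int i = 0; i < n; ++i) {
    const int v = oob_votes0[i] + oob_votes1[i];
    if (v == 0) {
      oob_prob[i] = NA_REAL;
      continue;
    }
    n_oob++;
    oob_prob[i] = (double)oob_votes1[i] / v;
    const int cls = oob_votes1[i] > oob_votes0[i] ? 1 : 0;
    if (cls != y[i]) wrong++;
  }
  const double oob_error = n_oob ? (double)wrong / n_oob : NA_REAL;

  NumericVector importance_out(p);
  for (int f = 0; f < p; ++f) importance_out[f] = imp[f] / ntree;
  NumericVector test_prob(ntest);
  for (int i = 0; i < ntest; ++i) test_prob[i] = test_votes[i] / ntree;

  return List::create(_["oob_error"] = oob_error,
                      _["n_oob"] = n_oob,
                      _["oob_prob"] = oob_prob,
                      _["importance"] = importance_out,
                      _["test_prob"] = test_prob);
}
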