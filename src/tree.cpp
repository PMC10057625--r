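#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact-greedy CART regression tree with squared-error impurity.
//
// rows: 0-based row indices into X/y used to grow the tree (a bootstrap
// sample may repeat rows). mtry: number of features considered per split,
// sampled without replacement via R's RNG so fits are reproducible under
// set.seed(). Splits must leave at least min_leaf rows on each side.
//
// Each feature's sample order is presorted once and partitioned stably at
// every split, so the per-node cost is linear in the node size instead of
// n log n - this is what keeps deep boosted trees affordable.
// [[Rcpp::export]]
List fit_tree_cpp(NumericMatrix X, NumericVector y, IntegerVector rows,
                  int min_leaf, int mtry) {
  const int p = X.ncol();
  const int n = rows.size();
  if (min_leaf < 1) min_leaf = 1;
  if (mtry < 1) mtry = 1;
  if (mtry > p) mtry = p;

  // slot s refers to sample rows[s]; cache its target and feature values
  std::vector<double> yv(n);
  for (int s = 0; s < n; ++s) yv[s] = y[rows[s]];

  // order[f * n + i]: slots sorted by feature f
  std::vector<int> order(static_cast<size_t>(p) * n);
  std::vector<int> tmp(n);
  for (int f = 0; f < p; ++f) {
    const double* Xf = &X(0, f);
    int* of = order.data() + static_cast<size_t>(f) * n;
    for (int s = 0; s < n; ++s) of[s] = s;
    std::sort(of, of + n, [&](int a, int b) {
      return Xf[rows[a]] < Xf[rows[b]];
    });
  }

  std::vector<int> feat;
  std::vector<double> thr, val;
  std::vector<int> left, right;
  auto new_node = [&]() {
    feat.push_back(-1);
    thr.push_back(0.0);
    val.push_back(0.0);
    left.push_back(-1);
    right.push_back(-1);
    return static_cast<int>(feat.size()) - 1;
  };

  struct Task { int node, lo, hi; };
  std::vector<Task> stack;
  std::vector<int> featidx(p);
  std::vector<char> goes_left(n);

  stack.push_back(Task{new_node(), 0, n});
  while (!stack.empty()) {
    Task t = stack.back();
    stack.pop_back();
    const int m = t.hi - t.lo;
    const int* o0 = order.data() + t.lo;  // feature 0's slots for this node
    double sum = 0.0;
    for (int i = 0; i < m; ++i) sum += yv[o0[i]];
    val[t.node] = sum / m;
    if (m < 2 * min_leaf || m < 2) continue;

    for (int j = 0; j < p; ++j) featidx[j] = j;
    for (int j = 0; j < mtry; ++j) {
      int k = j + static_cast<int>(unif_rand() * (p - j));
      if (k >= p) k = p - 1;
      std::swap(featidx[j], featidx[k]);
    }

    double best_score = sum * sum / m;  // score of not splitting
    double best_thr = 0.0;
    int best_f = -1;
    for (int j = 0; j < mtry; ++j) {
      const int f = featidx[j];
      const double* Xf = &X(0, f);
      const int* of = order.data() + static_cast<size_t>(f) * n + t.lo;
      double sl = 0.0;
      for (int i = 1; i < m; ++i) {
        sl += yv[of[i - 1]];
        if (i < min_leaf || m - i < min_leaf) continue;
        const double xl = Xf[rows[of[i - 1]]];
        const double xr = Xf[rows[of[i]]];
        if (xr <= xl) continue;  // tied values
        const double sr = sum - sl;
        const double score = sl * sl / i + sr * sr / (m - i);
        if (score > best_score) {
          best_score = score;
          best_f = f;
          best_thr = 0.5 * (xl + xr);
        }
      }
    }
    if (best_f < 0) continue;

    const double* Xb = &X(0, best_f);
    int n_left = 0;
    for (int i = 0; i < m; ++i) {
      const char gl = Xb[rows[o0[i]]] <= best_thr;
      goes_left[o0[i]] = gl;
      n_left += gl;
    }
    if (n_left == 0 || n_left == m) continue;

    // stable partition of every feature's slot order
    for (int f = 0; f < p; ++f) {
      int* of = order.data() + static_cast<size_t>(f) * n + t.lo;
      int a = 0, b = 0;
      for (int i = 0; i < m; ++i) {
        if (goes_left[of[i]]) of[a++] = of[i];
        else tmp[b++] = of[i];
      }
      std::copy(tmp.begin(), tmp.begin() + b, of + a);
    }

    feat[t.node] = best_f;
    thr[t.node] = best_thr;
    const int L = new_node();
    const int R = new_node();
    left[t.node] = L;
    right[t.node] = R;
    stack.push_back(Task{L, t.lo, t.lo + n_left});
    stack.push_back(Task{R, t.lo + n_left, t.hi});
  }

  return List::create(_["feature"] = wrap(feat), _["threshold"] = wrap(thr),
                      _["left"] = wrap(left), _["right"] = wrap(right),
                      _["value"] = wrap(val));
}

// Accumulated ensemble prediction: base + sum_t weights[t] * tree_t(x).
// Bagging passes weights = 1/B and base = 0; least-squares boosting passes
// weights = learning rate and base = mean(y_train).
// [[Rcpp::export]]
NumericVector predict_ensemble_cpp(List trees, NumericMatrix X,
                                   NumericVector weights, double base) {
  const int n = X.nrow();
  NumericVector out(n, base);
  const int B = trees.size();
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector feat = tr["feature"];
    NumericVector thr = tr["threshold"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector val = tr["value"];
    const double w = weights[b];
    for (int i = 0; i < n; ++i) {
      int node = 0;
      while (feat[node] >= 0)
        node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
      out[i] += w * val[node];
    }
  }
  return out;
}
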