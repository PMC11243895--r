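#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gini impurity of a two-class node.
static inline double gini2(double n0, double n1) {
  double n = n0 + n1;
  if (n <= 0) return 0.0;
  double p0 = n0 / n, p1 = n1 / n;
  return 1.0 - p0 * p0 - p1 * p1;
}

struct SplitResult {
  int feature;      // 0-based column, -1 = no impurity-reducing split
  double threshold; // midpoint between consecutive distinct values
  double impurity;  // sample-weighted child Gini
};

// Scan all candidate (feature, midpoint) splits for the rows in idx.
// Deterministic tie-breaking: features in column order, thresholds in
// increasing order; only strict improvements replace the incumbent.
static SplitResult scan_splits(const NumericMatrix& X, const IntegerVector& y,
                               const std::vector<int>& idx) {
  int n = idx.size();
  int p = X.ncol();
  double n1_tot = 0;
  for (int i = 0; i < n; ++i) n1_tot += y[idx[i]];
  double n0_tot = n - n1_tot;
  double parent = gini2(n0_tot, n1_tot);

  SplitResult best;
  best.feature = -1;
  best.threshold = NA_REAL;
  best.impurity = parent;

  std::vector<std::pair<double, int>> vals(n);
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) {
      vals[i] = std::make_pair(X(idx[i], j), y[idx[i]]);
    }
    std::sort(vals.begin(), vals.end());
    double l0 = 0, l1 = 0;
    for (int i = 0; i < n - 1; ++i) {
      if (vals[i].second == 1) l1 += 1; else l0 += 1;
      if (vals[i].first == vals[i + 1].first) continue;  // not a boundary
      double r0 = n0_tot - l0, r1 = n1_tot - l1;
      double w = ((l0 + l1) * gini2(l0, l1) + (r0 + r1) * gini2(r0, r1)) / n;
      if (w < best.impurity - 1e-12) {
        best.impurity = w;
        best.feature = j;
        best.threshold = (vals[i].first + vals[i + 1].first) / 2.0;
      }
    }
  }
  if (best.feature == -1) best.impurity = NA_REAL;
  return best;
}

// [[Rcpp::export(name = ".cpp_best_split")]]
List cpp_best_split(NumericMatrix X, IntegerVector y) {
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  SplitResult s = scan_splits(X, y, idx);
  return List::create(_["feature"] = s.feature + 1,  // 1-based, 0 = none
                      _["threshold"] = s.threshold,
                      _["impurity"] = s.impurity);
}

// Recursive CART growth over a flat node table.
struct TreeBuilder {
  const NumericMatrix& X;
  const IntegerVector& y;
  int min_samples;
  std::vector<int> feature, left, right, n0v, n1v, pred;
  std::vector<double> threshold, gini;

  TreeBuilder(const NumericMatrix& X_, const IntegerVector& y_, int ms)
    : X(X_), y(y_), min_samples(ms) {}

  int grow(std::vector<int>& idx) {
    int n = idx.size();
    double n1 = 0;
    for (int i = 0; i < n; ++i) n1 += y[idx[i]];
    double n0 = n - n1;
    int id = feature.size();
    feature.push_back(-1);
    threshold.push_back(NA_REAL);
    gini.push_back(gini2(n0, n1));
    n0v.push_back((int)n0);
    n1v.push_back((int)n1);
    // majority prediction; tie -> class 1 (fatigued, the majority state)
    pred.push_back(n1 >= n0 ? 1 : 0);
    left.push_back(-1);
    right.push_back(-1);

    bool pure = (n0 == 0 || n1 == 0);
    if (pure || n < min_samples) return id;
    SplitResult s = scan_splits(X, y, idx);
    if (s.feature < 0) return id;

    std::vector<int> lidx, ridx;
    lidx.reserve(n); ridx.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], s.feature) <= s.threshold) lidx.push_back(idx[i]);
      else ridx.push_back(idx[i]);
    }
    feature[id] = s.feature;
    threshold[id] = s.threshold;
    int l = grow(lidx);
    int r = grow(ridx);
    left[id] = l;
    right[id] = r;
    return id;
  }
};

// [[Rcpp::export(name = ".cpp_build_tree")]]
DataFrame cpp_build_tree(NumericMatrix X, IntegerVector y, int min_samples) {
  TreeBuilder tb(X, y, min_samples);
  std::vector<int> idx(X.nrow());
  for (int i = 0; i < (int)idx.size(); ++i) idx[i] = i;
  tb.grow(idx);
  int nn = tb.feature.size();
  IntegerVector f(nn), l(nn), r(nn), n0(nn), n1(nn), pr(nn);
  NumericVector th(nn), gi(nn);
  for (int i = 0; i < nn; ++i) {
    f[i] = tb.feature[i] + 1;  // 1-based, 0 = leaf
    th[i] = tb.threshold[i];
    gi[i] = tb.gini[i];
    n0[i] = tb.n0v[i];
    n1[i] = tb.n1v[i];
    pr[i] = tb.pred[i];
    l[i] = tb.left[i] + 1;     // 1-based, 0 = none
    r[i] = tb.right[i] + 1;
  }
  return DataFrame::create(_["feature"] = f, _["threshold"] = th,
                           _["gini"] = gi, _["n_alert"] = n0,
                           _["n_fatigued"] = n1, _["pred"] = pr,
                           _["left"] = l, _["right"] = r);
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
IntegerVector cpp_predict_tree(IntegerVector feature, NumericVector threshold,
                               IntegerVector left, IntegerVector right,
                               IntegerVector pred, NumericMatrix X) {
  int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feature[node] > 0) {
      if (X(i, feature[node] - 1) <= threshold[node]) node = left[node] - 1;
      else node = right[node] - 1;
    }
    out[i] = pred[node];
  }
  return out;
}
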