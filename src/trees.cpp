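// Weighted CART regression trees: the base learner behind the gradient
// boosting and random forest members of the habitat ensemble. Greedy
// splits minimise weighted squared error; mtry < d gives random-forest
// style feature subsampling at each node (uses R's RNG, so fits are
// reproducible under set.seed()).

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

struct TreeBuf {
  std::vector<int> feat, left, right;
  std::vector<double> thr, val;
};

static void build_node(const NumericMatrix& X, const NumericVector& y,
                       const NumericVector& w, std::vector<int>& idx,
                       int lo, int hi, int depth, int max_depth,
                       int min_obs, int mtry, TreeBuf& T) {
  int node = (int)T.feat.size();
  T.feat.push_back(-1); T.thr.push_back(0.0);
  T.left.push_back(-1); T.right.push_back(-1);

  double sw = 0.0, swy = 0.0;
  for (int i = lo; i < hi; ++i) { sw += w[idx[i]]; swy += w[idx[i]] * y[idx[i]]; }
  double mean = (sw > 0.0) ? swy / sw : 0.0;
  T.val.push_back(mean);

  int n = hi - lo;
  if (depth >= max_depth || n < 2 * min_obs || sw <= 0.0) return;

  int d = X.ncol();
  std::vector<int> feats(d);
  for (int j = 0; j < d; ++j) feats[j] = j;
  int ntry = (mtry > 0 && mtry < d) ? mtry : d;
  if (ntry < d) { // partial Fisher-Yates with R's RNG
    for (int j = 0; j < ntry; ++j) {
      int k = j + (int)(unif_rand() * (d - j));
      if (k >= d) k = d - 1;
      std::swap(feats[j], feats[k]);
    }
  }

  double best_gain = 1e-12;
  int best_feat = -1, best_pos = -1;
  double best_thr = 0.0;
  std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
  std::vector<int> best_ord;

  for (int jj = 0; jj < ntry; ++jj) {
    int j = feats[jj];
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return X(a, j) < X(b, j); });
    double lw = 0.0, lwy = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      int a = ord[i];
      lw += w[a]; lwy += w[a] * y[a];
      if (X(ord[i + 1], j) <= X(a, j)) continue;           // tie: no split here
      if (i + 1 < min_obs || n - i - 1 < min_obs) continue;
      double rw = sw - lw, rwy = swy - lwy;
      if (lw <= 0.0 || rw <= 0.0) continue;
      // gain = reduction in weighted SSE = lwy^2/lw + rwy^2/rw - swy^2/sw
      double gain = lwy * lwy / lw + rwy * rwy / rw - swy * swy / sw;
      if (gain > best_gain) {
        best_gain = gain; best_feat = j; best_pos = i;
        best_thr = 0.5 * (X(a, j) + X(ord[i + 1], j));
        best_ord = ord;
      }
    }
  }
  if (best_feat < 0) return;

  std::copy(best_ord.begin(), best_ord.end(), idx.begin() + lo);
  T.feat[node] = best_feat;
  T.thr[node] = best_thr;
  int mid = lo + best_pos + 1;
  T.left[node] = (int)T.feat.size();
  build_node(X, y, w, idx, lo, mid, depth + 1, max_depth, min_obs, mtry, T);
  T.right[node] = (int)T.feat.size();
  build_node(X, y, w, idx, mid, hi, depth + 1, max_depth, min_obs, mtry, T);
}

// [[Rcpp::export(name = ".cpp_fit_tree")]]
List cpp_fit_tree(NumericMatrix X, NumericVector y, NumericVector w,
                  int max_depth, int min_obs, int mtry) {
  int n = X.nrow();
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  TreeBuf T;
  build_node(X, y, w, idx, 0, n, 0, max_depth, min_obs, mtry, T);
  return List::create(_["feat"] = wrap(T.feat), _["thr"] = wrap(T.thr),
                      _["left"] = wrap(T.left), _["right"] = wrap(T.right),
                      _["val"] = wrap(T.val));
}

// [[Rcpp::export(name = ".cpp_predict_tree")]]
NumericVector cpp_predict_tree(List tree, NumericMatrix X) {
  IntegerVector feat = tree["feat"], left = tree["left"], right = tree["right"];
  NumericVector thr = tree["thr"], val = tree["val"];
  int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int node = 0;
    while (feat[node] >= 0)
      node = (X(i, feat[node]) <= thr[node]) ? left[node] : right[node];
    out[i] = val[node];
  }
  return out;
}
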