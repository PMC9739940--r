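#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Brute-force k-nearest neighbours of each row of `query` among rows of `ref`.
// Returns 1-based index matrix (m x k) and distance matrix, neighbours sorted
// by increasing distance; ties broken by row index (stable).
// [[Rcpp::export]]
List cpp_knn(NumericMatrix ref, NumericMatrix query, int k) {
  const int n = ref.nrow(), m = query.nrow(), d = ref.ncol();
  if (k > n) stop("k exceeds number of reference points");
  IntegerMatrix idx(m, k);
  NumericMatrix dist(m, k);
  std::vector<std::pair<double,int> > buf(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = query(i, c) - ref(j, c);
        s += t * t;
      }
      buf[j] = std::make_pair(s, j);
    }
    std::partial_sort(buf.begin(), buf.begin() + k, buf.end());
    for (int j = 0; j < k; ++j) {
      idx(i, j) = buf[j].second + 1;
      dist(i, j) = std::sqrt(buf[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// Distance from each row of A to its nearest row in B (and the index).
// [[Rcpp::export]]
List cpp_nn_dist(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow(), d = A.ncol();
  NumericVector dist(n);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf; int bj = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = A(i, c) - B(j, c);
        s += t * t;
      }
      if (s < best) { best = s; bj = j; }
    }
    dist[i] = std::sqrt(best);
    idx[i] = bj + 1;
  }
  return List::create(_["dist"] = dist, _["idx"] = idx);
}

// Iterative farthest-point sampling: greedily add the point maximising the
// distance to the already-selected set, starting from `start` (0-based).
// Returns 1-based indices of the n selected points.
// [[Rcpp::export]]
IntegerVector cpp_fps(NumericMatrix X, int n, int start) {
  const int N = X.nrow(), d = X.ncol();
  if (n > N) stop("cannot sample more points than available");
  IntegerVector out(n);
  std::vector<double> mind(N, R_PosInf);
  int cur = start;
  for (int s = 0; s < n; ++s) {
    out[s] = cur + 1;
    double best = -1.0; int bj = cur;
    for (int j = 0; j < N; ++j) {
      double ss = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = X(j, c) - X(cur, c);
        ss += t * t;
      }
      if (ss < mind[j]) mind[j] = ss;
      if (mind[j] > best) { best = mind[j]; bj = j; }
    }
    cur = bj;
  }
  return out;
}
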