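#include <Rcpp.h>
using namespace Rcpp;

// Metric codes: 0 = euclidean, 1 = squared euclidean, 2 = cityblock.
// Accumulation order over attributes is fixed (t = 0..d-1) so that the
// sequential and parallel paths, which both route through these kernels,
// produce bit-identical doubles.
static inline double pt_dist(const double* X, int n, int d,
                             int i, int a, int metric) {
  double acc = 0.0;
  for (int t = 0; t < d; ++t) {
    double dif = X[i + (size_t)t * n] - X[a + (size_t)t * n];
    acc += (metric == 2) ? std::fabs(dif) : dif * dif;
  }
  return (metric == 0) ? std::sqrt(acc) : acc;
}

// Greedy build-phase candidate scores: for each candidate a,
// sum over active points i of min(dmin[i], D(x_i, x_a)).
// dmin holds the distance to the nearest already-chosen medoid (Inf when
// none has been chosen yet).
// [[Rcpp::export]]
NumericVector cpp_build_scores(NumericMatrix X, LogicalVector active,
                               IntegerVector cand, NumericVector dmin,
                               int metric) {
  int n = X.nrow(), d = X.ncol(), m = cand.size();
  NumericVector out(m);
  const double* px = REAL(X);
  for (int c = 0; c < m; ++c) {
    int a = cand[c] - 1;
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!active[i]) continue;
      double dd = pt_dist(px, n, d, i, a, metric);
      double dm = dmin[i];
      s += (dd < dm) ? dd : dm;
    }
    out[c] = s;
  }
  return out;
}

// Distances from every row of X to row a (1-based). Inactive rows are
// computed too (callers mask them); cheap and keeps the kernel simple.
// [[Rcpp::export]]
NumericVector cpp_dists_to_point(NumericMatrix X, int a, int metric) {
  int n = X.nrow(), d = X.ncol();
  NumericVector out(n);
  const double* px = REAL(X);
  for (int i = 0; i < n; ++i) out[i] = pt_dist(px, n, d, i, a - 1, metric);
  return out;
}

// Nearest-medoid tags for the rows listed in `rows` (1-based). Ties break
// to the lowest medoid position j (strict < keeps the earlier j).
// [[Rcpp::export]]
IntegerVector cpp_assign(NumericMatrix X, IntegerVector rows,
                         IntegerVector medoids, int metric) {
  int n = X.nrow(), d = X.ncol(), m = rows.size(), k = medoids.size();
  IntegerVector out(m);
  const double* px = REAL(X);
  for (int r = 0; r < m; ++r) {
    int i = rows[r] - 1;
    double best = R_PosInf;
    int bj = 1;
    for (int j = 0; j < k; ++j) {
      double dd = pt_dist(px, n, d, i, medoids[j] - 1, metric);
      if (dd < best) { best = dd; bj = j + 1; }
    }
    out[r] = bj;
  }
  return out;
}

// Within-cluster sums: for each candidate a in `cand`, the sum of distances
// from a to every member of the cluster (members include a itself; the
// self-distance contributes 0).
// [[Rcpp::export]]
NumericVector cpp_cluster_sums(NumericMatrix X, IntegerVector members,
                               IntegerVector cand, int metric) {
  int n = X.nrow(), d = X.ncol(), m = members.size(), q = cand.size();
  NumericVector out(q);
  const double* px = REAL(X);
  for (int c = 0; c < q; ++c) {
    int a = cand[c] - 1;
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += pt_dist(px, n, d, members[i] - 1, a, metric);
    out[c] = s;
  }
  return out;
}

// Objective cost: sum over active points of the distance to the nearest
// medoid.
// [[Rcpp::export]]
double cpp_objective(NumericMatrix X, LogicalVector active,
                     IntegerVector medoids, int metric) {
  int n = X.nrow(), d = X.ncol(), k = medoids.size();
  const double* px = REAL(X);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    if (!active[i]) continue;
    double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      double dd = pt_dist(px, n, d, i, medoids[j] - 1, metric);
      if (dd < best) best = dd;
    }
    total += best;
  }
  return total;
}
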