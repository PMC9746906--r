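// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

static double kl_divergence(const mat& V, const mat& WH) {
  // generalized KL: sum(V*log(V/WH) - V + WH), with 0*log(0) = 0
  double d = 0.0;
  for (uword j = 0; j < V.n_cols; ++j) {
    for (uword i = 0; i < V.n_rows; ++i) {
      double v = V(i, j), wh = WH(i, j);
      if (v > 0.0) d += v * std::log(v / wh) - v;
      d += wh;
    }
  }
  return d;
}

// Multiplicative-update NMF under generalized Kullback-Leibler divergence
// (Brunet variant). V (n x m) >= 0, W (n x r), H (r x m). Convergence when the
// relative change of the objective over a 10-iteration window drops below tol.
// [[Rcpp::export]]
Rcpp::List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
  const double eps = 1e-16;
  mat WH = W * H;
  double obj = kl_divergence(V, WH);
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update: H <- H * (W' (V/WH)) / (W' 1)
    mat Q = V / (WH + eps);
    H %= (W.t() * Q);
    H.each_col() /= (sum(W, 0).t() + eps);
    WH = W * H;
    // W update: W <- W * ((V/WH) H') / (1 H')
    Q = V / (WH + eps);
    W %= (Q * H.t());
    W.each_row() /= (sum(H, 1).t() + eps);
    WH = W * H;
    if (it % 10 == 0) {
      // per-iteration relative change, averaged over the 10-iteration window
      double obj_new = kl_divergence(V, WH);
      double denom = std::abs(obj) > eps ? std::abs(obj) : eps;
      if (std::abs(obj - obj_new) / (10.0 * denom) < tol) {
        obj = obj_new; break;
      }
      obj = obj_new;
    }
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("divergence") = kl_divergence(V, W * H),
                            Rcpp::Named("iterations") = std::min(it, max_iter));
}

// In-place accumulation for consensus clustering: for the subsampled items
// idx (0-based) with cluster labels lab, add 1 to conn[i,j] when co-clustered
// and to count[i,j] when co-sampled. Matrices are modified by reference.
// [[Rcpp::export]]
void accumulate_consensus_cpp(Rcpp::NumericMatrix conn, Rcpp::NumericMatrix count,
                              const Rcpp::IntegerVector& idx,
                              const Rcpp::IntegerVector& lab,
                              bool update_count) {
  const int m = idx.size();
  // column-major friendly: the inner loop walks rows of one column
  for (int b = 0; b < m; ++b) {
    const int ib = idx[b];
    const int lb = lab[b];
    double* conn_col = &conn(0, ib);
    double* count_col = &count(0, ib);
    for (int a = 0; a < m; ++a) {
      const int ia = idx[a];
      if (update_count) count_col[ia] += 1.0;
      if (lab[a] == lb) conn_col[ia] += 1.0;
    }
  }
}
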