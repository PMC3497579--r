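#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Felsenstein pruning log-likelihood for a k-state continuous-time Markov
// chain on a rooted tree. Edges must be supplied so that every child appears
// as a parent only in later... i.e. in postorder (children before parents).
// leaf_lik: nnode x k matrix of partial likelihoods; leaf rows hold the
// observed-state indicator, internal rows are ignored (reset to 1).

// [[Rcpp::export]]
double ctmc_loglik_cpp(const arma::mat& Q,
                       const arma::imat& edges,   // postorder, cols: parent, child (1-based)
                       const arma::vec& lens,
                       const arma::mat& leaf_lik,
                       const arma::uvec& is_leaf, // per node 0/1
                       int root,
                       const arma::vec& root_dist) {
  const int k = Q.n_cols;
  const int nnode = leaf_lik.n_rows;
  arma::mat part(nnode, k);
  double logscale = 0.0;
  for (int v = 0; v < nnode; ++v) {
    if (is_leaf[v]) part.row(v) = leaf_lik.row(v); else part.row(v).ones();
  }
  for (arma::uword e = 0; e < edges.n_rows; ++e) {
    int parent = edges(e, 0) - 1, child = edges(e, 1) - 1;
    arma::mat P = arma::expmat(Q * lens[e]);
    arma::rowvec msg = part.row(child) * P.t();  // msg[s] = sum_c P(s->c) L_child[c]
    part.row(parent) %= msg;
    double mx = part.row(parent).max();
    if (mx > 0 && mx < 1e-200) { part.row(parent) /= mx; logscale += std::log(mx); }
  }
  double lik = arma::dot(part.row(root - 1).t(), root_dist);
  if (lik <= 0) return -std::numeric_limits<double>::infinity();
  return std::log(lik) + logscale;
}
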