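// Felsenstein pruning likelihood for a K-state CTMC on a rooted binary
// tree, with the FitzJohn-Maddison ("maddfitz") root treatment: root state
// weights proportional to the root conditional likelihoods.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Transition probability matrices for a set of branch lengths.
// Uses the eigendecomposition of Q when well conditioned, otherwise falls
// back to scaling-and-squaring per branch.
static void branch_probs(const arma::mat& Q, const arma::vec& t,
                         std::vector<arma::mat>& out) {
  const arma::uword K = Q.n_rows;
  arma::cx_vec eval;
  arma::cx_mat evec;
  bool ok = arma::eig_gen(eval, evec, Q);
  arma::cx_mat vinv;
  if (ok) ok = arma::inv(vinv, evec);
  if (ok) {
    // reconstruction check guards near-defective matrices
    arma::mat recon = arma::real(evec * arma::diagmat(eval) * vinv);
    double scale = arma::norm(Q, "inf");
    if (scale < 1e-12) scale = 1.0;
    if (arma::norm(recon - Q, "inf") / scale > 1e-9) ok = false;
  }
  out.resize(t.n_elem);
  for (arma::uword e = 0; e < t.n_elem; ++e) {
    arma::mat P;
    if (ok) {
      P = arma::real(evec * arma::diagmat(arma::exp(eval * t[e])) * vinv);
    } else {
      P = arma::expmat(Q * t[e]);
    }
    P.clamp(0.0, 1.0);
    // renormalize rows (guards tiny eigen round-off)
    for (arma::uword i = 0; i < K; ++i) {
      double s = arma::accu(P.row(i));
      if (s > 0) P.row(i) /= s;
    }
    out[e] = P;
  }
}

// edge: E x 2 (1-based, parent/child), ordered postorder (children before
// parents). tip_state: 1..K per tip (tips are nodes 1..n_tip).
// [[Rcpp::export]]
double mk_pruning_loglik_cpp(const arma::mat& Q,
                             const arma::imat& edge,
                             const arma::vec& edge_length,
                             const int n_tip,
                             const arma::ivec& tip_state) {
  const arma::uword K = Q.n_rows;
  const arma::uword E = edge.n_rows;
  const arma::uword n_node = E + 1;

  std::vector<arma::mat> P;
  branch_probs(Q, edge_length, P);

  arma::mat L(n_node, K, arma::fill::ones);
  for (int i = 0; i < n_tip; ++i) {
    L.row(i).zeros();
    L(i, tip_state[i] - 1) = 1.0;
  }
  double logscale = 0.0;
  for (arma::uword e = 0; e < E; ++e) {
    const arma::uword a = edge(e, 0) - 1, b = edge(e, 1) - 1;
    arma::rowvec v = L.row(b) * P[e].t();  // v_i = sum_j P(i,j) L_b(j)
    double m = v.max();
    if (m <= 0) return R_NegInf;
    v /= m;
    logscale += std::log(m);
    L.row(a) %= v;
  }
  const arma::uword root = n_tip;  // 0-based index of node n_tip+1
  arma::rowvec Lr = L.row(root);
  double s1 = arma::accu(Lr), s2 = arma::accu(Lr % Lr);
  if (s1 <= 0) return R_NegInf;
  return std::log(s2 / s1) + logscale;
}
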