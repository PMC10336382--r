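// Forward simulation of a CTMC character down a tree, returning the full
// piecewise-constant history as flattened segments grouped by (original)
// edge index.

#include <Rcpp.h>
using namespace Rcpp;

// edge_pre: E x 2, 1-based, preorder (parents before children);
// orig_idx: original edge index (1-based) of each preorder row.
// [[Rcpp::export]]
List sim_discrete_cpp(const IntegerMatrix edge_pre,
                      const NumericVector elen_pre,
                      const IntegerVector orig_idx,
                      const int n_node, const int n_tip,
                      const NumericMatrix Q, const int root_state) {
  RNGScope scope;
  const int E = edge_pre.nrow();
  const int K = Q.nrow();
  IntegerVector node_state(n_node);
  node_state[n_tip] = root_state;  // root is node n_tip + 1 (1-based)
  std::vector<std::vector<int> > seg_st(E);
  std::vector<std::vector<double> > seg_du(E);
  for (int e = 0; e < E; ++e) {
    const int a = edge_pre(e, 0) - 1, b = edge_pre(e, 1) - 1;
    const int o = orig_idx[e] - 1;
    int s = node_state[a] - 1;
    double t_rem = elen_pre[e];
    for (;;) {
      double rate = -Q(s, s);
      double dt = (rate <= 0) ? R_PosInf : R::rexp(1.0 / rate);
      if (dt >= t_rem) {
        seg_st[o].push_back(s + 1);
        seg_du[o].push_back(t_rem);
        break;
      }
      seg_st[o].push_back(s + 1);
      seg_du[o].push_back(dt);
      t_rem -= dt;
      // jump: choose next state with prob Q[s, j] / rate
      double u = R::runif(0.0, 1.0) * rate;
      double acc = 0.0;
      int next = -1;
      for (int j = 0; j < K; ++j) {
        if (j == s) continue;
        acc += Q(s, j);
        if (u <= acc) { next = j; break; }
      }
      if (next < 0) next = (s == K - 1) ? K - 2 : K - 1;
      s = next;
    }
    node_state[b] = s + 1;
  }
  int total = 0;
  for (int e = 0; e < E; ++e) total += seg_st[e].size();
  IntegerVector br(total), st(total);
  NumericVector du(total);
  int k = 0;
  for (int e = 0; e < E; ++e)
    for (size_t i = 0; i < seg_st[e].size(); ++i) {
      br[k] = e + 1;
      st[k] = seg_st[e][i];
      du[k] = seg_du[e][i];
      ++k;
    }
  return List::create(_["node_state"] = node_state, _["br"] = br,
                      _["st"] = st, _["du"] = du);
}
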