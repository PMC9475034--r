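#include <Rcpp.h>
using namespace Rcpp;

// Current-flow (random-walk) betweenness from the Laplacian pseudoinverse.
// For each source/sink pair (s,t) a unit current is injected; the node
// potentials are p_v = Linv(v,s) - Linv(v,t) and the current on edge (v,w)
// is W(v,w) * (p_v - p_w). A node's throughput is half the absolute
// current over its incident edges; endpoints are excluded. Scores are
// normalized by the (n-1)(n-2)/2 pairs not involving the node.
// [[Rcpp::export]]
NumericVector cfb_from_linv(NumericMatrix W, NumericMatrix Linv) {
  int n = W.nrow();
  NumericVector out(n);
  for (int s = 0; s < n - 1; ++s) {
    for (int t = s + 1; t < n; ++t) {
      for (int v = 0; v < n; ++v) {
        if (v == s || v == t) continue;
        double pv = Linv(v, s) - Linv(v, t);
        double tau = 0.0;
        for (int w = 0; w < n; ++w) {
          double wt = W(v, w);
          if (wt > 0.0) {
            double pw = Linv(w, s) - Linv(w, t);
            tau += wt * std::fabs(pv - pw);
          }
        }
        out[v] += 0.5 * tau;
      }
    }
  }
  double norm = (double)(n - 1) * (double)(n - 2) / 2.0;
  if (norm > 0) {
    for (int v = 0; v < n; ++v) out[v] /= norm;
  }
  return out;
}
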