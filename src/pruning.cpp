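// Felsenstein pruning over the 4 joint states of two binary traits.
// PP holds vec(P(t_k)) per edge (column-major 4x4), edges are processed in
// postorder so child partials are complete before their parent's.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
double pruning_core_cpp(IntegerMatrix edge, NumericMatrix PP,
                        NumericMatrix tip_partials, int ntip, int nnode,
                        IntegerVector postorder, NumericVector pi_root) {
  int ntot = ntip + nnode;
  std::vector<double> part(4 * ntot, 1.0);
  for (int i = 0; i < ntip; ++i)
    for (int j = 0; j < 4; ++j)
      part[4 * i + j] = tip_partials(i, j);

  double scale_log = 0.0;
  for (int e = 0; e < postorder.size(); ++e) {
    int k = postorder[e] - 1;
    int par = edge(k, 0) - 1, chd = edge(k, 1) - 1;
    double v[4];
    for (int i = 0; i < 4; ++i) {
      double s = 0.0;
      for (int j = 0; j < 4; ++j) s += PP(i + 4 * j, k) * part[4 * chd + j];
      v[i] = s;
    }
    double m = 0.0;
    for (int i = 0; i < 4; ++i) {
      part[4 * par + i] *= v[i];
      if (part[4 * par + i] > m) m = part[4 * par + i];
    }
    if (m > 0.0 && m < 1e-12) {
      for (int i = 0; i < 4; ++i) part[4 * par + i] /= m;
      scale_log += std::log(m);
    }
  }
  double lik = 0.0;
  for (int i = 0; i < 4; ++i) lik += pi_root[i] * part[4 * ntip + i];
  return std::log(lik) + scale_log;
}
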