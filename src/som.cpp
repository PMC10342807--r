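#include <Rcpp.h>
using namespace Rcpp;

// Competitive-learning loop for a square-lattice self-organising map whose
// weight vectors live in sample space. Each presented gene vector pulls all
// node weights toward itself with a Gaussian lattice-neighbourhood
// attenuation around the best-matching (Euclidean-nearest) node.
//
// W:     nodes x samples weight matrix (modified copy returned)
// X:     genes x samples expression matrix (rows are presented vectors)
// order: 0-based gene indices, one per presentation, concatenated epochs
// ci,cj: lattice coordinates per node
// delta, sigma: per-presentation step size and neighbourhood width
// kernel: 0 = Gaussian on squared lattice distance (default),
//         1 = literal squared difference of squared node norms
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix W, NumericMatrix X,
                            IntegerVector order, IntegerVector ci,
                            IntegerVector cj, NumericVector delta,
                            NumericVector sigma, int kernel) {
  const int nodes = W.nrow(), ns = W.ncol(), T = order.size();
  NumericMatrix Wout = clone(W);
  for (int t = 0; t < T; ++t) {
    const int g = order[t];
    int best = 0;
    double bestd = R_PosInf;
    for (int k = 0; k < nodes; ++k) {
      double d = 0.0;
      for (int s = 0; s < ns; ++s) {
        const double e = X(g, s) - Wout(k, s);
        d += e * e;
      }
      if (d < bestd) { bestd = d; best = k; }
    }
    const double s2 = sigma[t] * sigma[t];
    for (int k = 0; k < nodes; ++k) {
      double h;
      if (kernel == 0) {
        const double di = ci[k] - ci[best];
        const double dj = cj[k] - cj[best];
        h = std::exp(-(di * di + dj * dj) / s2);
      } else {
        const double q =
            (double)(ci[k] * ci[k] + cj[k] * cj[k]) -
            (double)(ci[best] * ci[best] + cj[best] * cj[best]);
        h = std::exp(-(q * q) / s2);
      }
      const double dh = delta[t] * h;
      if (dh == 0.0) continue;
      for (int s = 0; s < ns; ++s)
        Wout(k, s) += dh * (X(g, s) - Wout(k, s));
    }
  }
  return Wout;
}
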