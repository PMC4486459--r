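// Felsenstein pruning over the 61 sense-codon states, vectorized over site
// patterns and omega classes. Transition probabilities come from a spectral
// decomposition of the (reversible) rate matrix done in R; this kernel only
// exponentiates eigenvalues, assembles P per branch and runs the postorder
// product with per-class log scaling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// lambda: 61 x K eigenvalues per class
// U, Uinv: 61 x 61 x K decomposition per class (P = U diag(exp(l t)) Uinv)
// edge: nedge x 2, 1-based ape-style (parent, child), postorder
// blens: per-edge branch lengths (expected substitutions per codon)
// tips: ntip x npat integer codon states, 1..61, or 0 for gap/ambiguous
// pi: 61 stationary frequencies
// returns npat x K matrix of per-pattern per-class log-likelihoods
// [[Rcpp::export]]
arma::mat codon_class_loglik(const arma::mat& lambda, const arma::cube& U,
                             const arma::cube& Uinv, const arma::imat& edge,
                             const arma::vec& blens, const arma::imat& tips,
                             const arma::vec& pi, int nnode) {
  const int K = lambda.n_cols;
  const int npat = tips.n_cols;
  const int ntip = tips.n_rows;
  const int ns = lambda.n_rows;
  const int nedge = edge.n_rows;

  mat out(npat, K);

  for (int k = 0; k < K; ++k) {
    std::vector<mat> L(nnode);
    std::vector<bool> seen(nnode, false);
    rowvec logscale(npat, fill::zeros);

    for (int e = 0; e < nedge; ++e) {
      int parent = edge(e, 0) - 1;
      int child = edge(e, 1) - 1;

      mat P = U.slice(k) * diagmat(exp(lambda.col(k) * blens(e))) *
              Uinv.slice(k);
      P.transform([](double v) { return v < 0.0 ? 0.0 : v; });

      mat Lc;
      if (child < ntip) {
        Lc.zeros(ns, npat);
        for (int s = 0; s < npat; ++s) {
          int st = tips(child, s);
          if (st > 0)
            Lc(st - 1, s) = 1.0;
          else
            Lc.col(s).ones();
        }
      } else {
        Lc = L[child];
        L[child].reset();
      }

      mat contrib = P * Lc;
      if (!seen[parent]) {
        L[parent] = contrib;
        seen[parent] = true;
      } else {
        L[parent] %= contrib;
        // rescale to dodge underflow on deep/large trees
        rowvec m = max(L[parent], 0);
        m.transform([](double v) { return v <= 0.0 ? 1.0 : v; });
        L[parent].each_row() /= m;
        logscale += log(m);
      }
    }

    int root = edge(nedge - 1, 0) - 1;
    rowvec sitelik = pi.t() * L[root];
    sitelik.transform([](double v) { return v <= 0.0 ? 1e-300 : v; });
    out.col(k) = (log(sitelik) + logscale).t();
  }
  return out;
}
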