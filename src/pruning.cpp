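// Felsenstein pruning for reversible codon mixture models.
//
// The generator Q of each mixture class is reversible with respect to pi
// (Q_ij = pi_j * s_ij with s symmetric), so B = D^{1/2} Q D^{-1/2} is
// symmetric and P(t) = A exp(L t) Ainv with A = D^{-1/2} U,
// Ainv = U^T D^{1/2}.  One symmetric eigendecomposition per class serves
// every branch.  Tip edges never build the full transition matrix: for an
// observed codon c the child contribution is the single column
// A (exp(L t) % Ainv[, c]).  Per-pattern scaling keeps partial likelihoods
// in range on large trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// edges: n_edges x 2 (parent, child), 1-based, postorder (every child edge
//        appears before the edge above its parent); root = edges(last, 0).
// blen:  branch lengths (expected substitutions per codon), one per edge.
// tipstate: n_tips x n_patterns integer matrix; codon index 1..61, 0 = missing.
// Qs:    61 x 61 x n_class cube of normalized generators.
// pi:    61 sense-codon frequencies.
//
// Returns n_patterns x n_class matrix of per-pattern log-likelihoods.
// [[Rcpp::export(name = ".pruning_loglik")]]
arma::mat pruning_loglik(const arma::imat& edges,
                         const arma::vec& blen,
                         const arma::imat& tipstate,
                         const arma::cube& Qs,
                         const arma::vec& pi) {
  const uword n_edges = edges.n_rows;
  const uword n_tips = tipstate.n_rows;
  const uword npat = tipstate.n_cols;
  const uword n_class = Qs.n_slices;
  const uword n_nodes = n_tips + n_edges; // upper bound on node ids

  const vec sqp = sqrt(pi);
  const vec isqp = 1.0 / sqp;
  const uword root = (uword)edges(n_edges - 1, 0) - 1;

  mat out(npat, n_class);

  for (uword cl = 0; cl < n_class; ++cl) {
    mat B = Qs.slice(cl);
    B.each_col() %= sqp;   // D^{1/2} Q
    B.each_row() %= isqp.t(); // ... D^{-1/2}
    B = 0.5 * (B + B.t());
    vec lam;
    mat U;
    eig_sym(lam, U, B);
    mat A = U.each_col() % isqp;       // D^{-1/2} U
    mat Ainv = U.t();
    Ainv.each_row() %= sqp.t();        // U^T D^{1/2}

    // partial likelihoods per node (allocated lazily) and per-pattern log scale
    std::vector<mat> partial(n_nodes);
    std::vector<bool> touched(n_nodes, false);
    rowvec logscale(npat, fill::zeros);

    for (uword e = 0; e < n_edges; ++e) {
      const uword par = (uword)edges(e, 0) - 1;
      const uword chl = (uword)edges(e, 1) - 1;
      const vec ex = exp(lam * blen(e));

      mat contrib;
      if (chl < n_tips) {
        // tip child: look up needed columns of P only
        contrib.set_size(61, npat);
        // cache per observed state (0 = missing handled separately)
        std::vector<vec> colcache(62);
        std::vector<bool> have(62, false);
        for (uword j = 0; j < npat; ++j) {
          const int s = tipstate(chl, j);
          if (s == 0) {
            contrib.col(j).ones();
          } else {
            if (!have[s]) {
              colcache[s] = A * (ex % Ainv.col(s - 1));
              have[s] = true;
            }
            contrib.col(j) = colcache[s];
          }
        }
      } else {
        // internal child: rescale its completed partial once, then one gemm
        rowvec mx = max(partial[chl], 0);
        mx.transform([](double v) { return v > 0 ? v : 1.0; });
        partial[chl].each_row() /= mx;
        logscale += log(mx);
        mat P = (A.each_row() % ex.t()) * Ainv;
        contrib = P * partial[chl];
      }

      // eigendecomposition roundoff can leave tiny negative entries
      contrib.clamp(0.0, datum::inf);

      if (!touched[par]) {
        partial[par] = contrib;
        touched[par] = true;
      } else {
        partial[par] %= contrib;
      }
      if (chl >= n_tips) partial[chl].reset();
    }

    rowvec rootlik = pi.t() * partial[root];
    out.col(cl) = (logscale + log(rootlik)).t();
  }
  return out;
}
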