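// Felsenstein pruning for amino-acid site likelihoods under a reversible
// replacement model, evaluated at several rate multipliers (discrete gamma
// categories). Partial likelihoods are rescaled per site to avoid underflow
// on large trees.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// tips   : n_sites x n_tips integer matrix, states 1..20, 0 = missing
// edge   : n_edges x 2 (parent, child), 1-based, postorder (children first)
// elen   : branch lengths (expected substitutions per site)
// U, Uinv, lam : eigensystem of the rate matrix Q = U diag(lam) Uinv
// pi     : root (stationary) frequencies
// rates  : rate multipliers, one per category
// returns n_sites x n_categories matrix of per-site log-likelihoods
// [[Rcpp::export]]
arma::mat site_loglik_cpp(const arma::imat& tips, const arma::imat& edge,
                          const arma::vec& elen, const int n_nodes,
                          const arma::mat& U, const arma::mat& Uinv,
                          const arma::vec& lam, const arma::vec& pi,
                          const arma::vec& rates) {
  const uword S = tips.n_rows, T = tips.n_cols, E = edge.n_rows,
              C = rates.n_elem;
  mat out(S, C);
  const int root = edge(E - 1, 0) - 1;

  for (uword c = 0; c < C; ++c) {
    std::vector<mat> part(n_nodes);
    std::vector<vec> lsc(n_nodes);
    std::vector<bool> seen(n_nodes, false);

    for (uword e = 0; e < E; ++e) {
      const int pa = edge(e, 0) - 1, ch = edge(e, 1) - 1;
      mat P = U * diagmat(exp(lam * (elen(e) * rates(c)))) * Uinv;
      P.elem(find(P < 0)).zeros();

      mat contrib(S, 20);
      vec chlsc;
      if (ch < (int)T) {
        for (uword s = 0; s < S; ++s) {
          const int st = tips(s, ch);
          if (st > 0) contrib.row(s) = P.col(st - 1).t();
          else contrib.row(s).ones();
        }
        chlsc = vec(S, fill::zeros);
      } else {
        contrib = part[ch] * P.t();
        chlsc = lsc[ch];
        part[ch].reset();
      }

      if (!seen[pa]) {
        part[pa] = contrib; lsc[pa] = chlsc; seen[pa] = true;
      } else {
        part[pa] %= contrib; lsc[pa] += chlsc;
      }

      // rescale rows drifting toward under/overflow
      vec m = max(part[pa], 1);
      for (uword s = 0; s < S; ++s) {
        const double ms = m(s);
        if (ms > 0 && (ms < 1e-120 || ms > 1e120)) {
          part[pa].row(s) /= ms;
          lsc[pa](s) += std::log(ms);
        }
      }
    }

    vec lik = part[root] * pi;
    for (uword s = 0; s < S; ++s)
      out(s, c) = (lik(s) > 0 ? std::log(lik(s)) : -datum::inf) + lsc[root](s);
  }
  return out;
}
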