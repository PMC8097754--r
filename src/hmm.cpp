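#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Log-space Viterbi over a generic state space.
//
// logE   : S x L matrix of per-marker log emission likelihoods
// logT   : S x S x (L-1) cube, logT(i, j, l) = log P(state_{l+1} = j | state_l = i)
// logpi  : length-S vector of initial log probabilities
//
// Ties are broken towards the lowest state index, both at the final state and
// at every backtrack choice, so decoding is reproducible.
// [[Rcpp::export]]
List hmm_viterbi_cpp(const arma::mat& logE, const arma::cube& logT,
                     const arma::vec& logpi) {
  const arma::uword S = logE.n_rows, L = logE.n_cols;
  if (logpi.n_elem != S) stop("prior length does not match state count");
  if (L > 1 && (logT.n_slices != L - 1 || logT.n_rows != S || logT.n_cols != S))
    stop("transition cube dimensions do not match emissions");

  arma::vec delta = logpi + logE.col(0);
  arma::umat psi(S, L, arma::fill::zeros);

  for (arma::uword l = 1; l < L; ++l) {
    arma::vec delta_new(S);
    for (arma::uword j = 0; j < S; ++j) {
      double best = -arma::datum::inf;
      arma::uword arg = 0;
      for (arma::uword i = 0; i < S; ++i) {
        const double v = delta(i) + logT(i, j, l - 1);
        if (v > best) { best = v; arg = i; }  // strict '>' keeps lowest i on ties
      }
      delta_new(j) = best + logE(j, l);
      psi(j, l) = arg;
    }
    delta = delta_new;
  }

  arma::uword last = 0;
  double best = -arma::datum::inf;
  for (arma::uword j = 0; j < S; ++j) {
    if (delta(j) > best) { best = delta(j); last = j; }
  }

  IntegerVector path(L);
  arma::uword cur = last;
  path[L - 1] = static_cast<int>(cur) + 1;
  for (arma::uword l = L - 1; l > 0; --l) {
    cur = psi(cur, l);
    path[l - 1] = static_cast<int>(cur) + 1;
  }

  return List::create(_["path"] = path, _["logprob"] = best);
}

// Scaled forward-backward. E, T and pi are on the probability scale; the
// per-marker scaling constants give the log-likelihood without underflow.
//
// Returns gamma (S x L posterior state probabilities, columns sum to 1) and
// the log-likelihood of the observation sequence.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(const arma::mat& E, const arma::cube& T,
                              const arma::vec& pi) {
  const arma::uword S = E.n_rows, L = E.n_cols;
  if (pi.n_elem != S) stop("prior length does not match state count");
  if (L > 1 && (T.n_slices != L - 1 || T.n_rows != S || T.n_cols != S))
    stop("transition cube dimensions do not match emissions");

  arma::mat alpha(S, L), beta(S, L);
  arma::vec scale(L);

  alpha.col(0) = pi % E.col(0);
  scale(0) = arma::accu(alpha.col(0));
  if (scale(0) <= 0.0) stop("observation sequence has zero likelihood");
  alpha.col(0) /= scale(0);

  for (arma::uword l = 1; l < L; ++l) {
    alpha.col(l) = (T.slice(l - 1).t() * alpha.col(l - 1)) % E.col(l);
    scale(l) = arma::accu(alpha.col(l));
    if (scale(l) <= 0.0) stop("observation sequence has zero likelihood");
    alpha.col(l) /= scale(l);
  }

  beta.col(L - 1).ones();
  for (arma::uword l = L - 1; l > 0; --l) {
    beta.col(l - 1) = T.slice(l - 1) * (E.col(l) % beta.col(l)) / scale(l);
  }

  arma::mat gamma = alpha % beta;
  for (arma::uword l = 0; l < L; ++l) gamma.col(l) /= arma::accu(gamma.col(l));

  return List::create(_["gamma"] = gamma,
                      _["loglik"] = arma::accu(arma::log(scale)));
}
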