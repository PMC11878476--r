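// Linear-chain CRF primitives: Viterbi decoding and the log-partition
// (forward algorithm in log space). Shared by the tagger and exposed to R
// so they can be checked against brute-force enumeration.
// Conventions: emissions are T x L (tokens x tags); transitions are
// (L+2) x (L+2) with row/col L (0-based) = START and L+1 = STOP.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static double logsumexp_vec(const arma::vec& x) {
  double m = x.max();
  if (!std::isfinite(m)) return m;
  return m + std::log(arma::sum(arma::exp(x - m)));
}

// [[Rcpp::export]]
List cpp_crf_viterbi(const arma::mat& emissions, const arma::mat& transitions) {
  const int T = emissions.n_rows, L = emissions.n_cols;
  const int START = L, STOP = L + 1;
  if ((int)transitions.n_rows != L + 2 || (int)transitions.n_cols != L + 2)
    stop("transition matrix must be (L+2) x (L+2)");
  arma::mat delta(T, L);
  arma::imat psi(T, L);
  for (int j = 0; j < L; ++j)
    delta(0, j) = transitions(START, j) + emissions(0, j);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < L; ++j) {
      double best = -arma::datum::inf; int arg = 0;
      for (int i = 0; i < L; ++i) {
        double s = delta(t - 1, i) + transitions(i, j);
        if (s > best) { best = s; arg = i; }  // strict >: ties keep lowest index
      }
      delta(t, j) = best + emissions(t, j);
      psi(t, j) = arg;
    }
  }
  double best = -arma::datum::inf; int arg = 0;
  for (int j = 0; j < L; ++j) {
    double s = delta(T - 1, j) + transitions(j, STOP);
    if (s > best) { best = s; arg = j; }
  }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;  // 1-based for R
  return List::create(_["path"] = path, _["score"] = best);
}

// [[Rcpp::export]]
double cpp_crf_log_partition(const arma::mat& emissions, const arma::mat& transitions) {
  const int T = emissions.n_rows, L = emissions.n_cols;
  const int START = L, STOP = L + 1;
  if ((int)transitions.n_rows != L + 2 || (int)transitions.n_cols != L + 2)
    stop("transition matrix must be (L+2) x (L+2)");
  arma::vec alpha = transitions.submat(START, 0, START, L - 1).t() + emissions.row(0).t();
  arma::vec nxt(L);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < L; ++j)
      nxt(j) = logsumexp_vec(alpha + transitions.submat(0, j, L - 1, j)) + emissions(t, j);
    alpha = nxt;
  }
  return logsumexp_vec(alpha + transitions.submat(0, STOP, L - 1, STOP));
}
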