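// Skip-gram word embeddings with negative sampling, single-threaded and
// deterministic under a seed. Sentences arrive as 0-based word-id vectors
// over a vocabulary already filtered by min_count (done in R).
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;

static inline double sigmoid_clip(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// [[Rcpp::export]]
arma::mat cpp_sgns_train(const List& sentences, const arma::vec& counts, int dim,
                         int window, int negative, int epochs, double alpha,
                         int seed) {
  const int V = counts.n_elem;
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // unigram^0.75 table for negative sampling
  arma::vec probs = arma::pow(counts, 0.75);
  probs /= arma::sum(probs);
  arma::vec cum = arma::cumsum(probs);
  auto draw_neg = [&]() {
    double u = unif(rng);
    return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
  };

  arma::mat syn0(dim, V), syn1(dim, V, arma::fill::zeros);
  for (arma::uword i = 0; i < syn0.n_elem; ++i)
    syn0(i) = (unif(rng) - 0.5) / dim;

  long total_pairs = 0;
  for (int s = 0; s < sentences.size(); ++s)
    total_pairs += Rf_length(sentences[s]);
  total_pairs = std::max(1L, total_pairs * (long)epochs);
  long seen = 0;

  arma::vec errv(dim);
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sent = sentences[s];
      const int n = sent.size();
      for (int t = 0; t < n; ++t) {
        ++seen;
        double lr = alpha * std::max(1.0 - (double)seen / (total_pairs + 1.0), 1e-4);
        int b = (int)(unif(rng) * window);  // dynamic window shrink
        for (int off = b - window; off <= window - b; ++off) {
          if (off == 0) continue;
          int c = t + off;
          if (c < 0 || c >= n) continue;
          int center = sent[t], context = sent[c];
          errv.zeros();
          for (int k = 0; k <= negative; ++k) {
            int target; double label;
            if (k == 0) { target = context; label = 1.0; }
            else {
              target = draw_neg();
              if (target == context) continue;
              label = 0.0;
            }
            double f = sigmoid_clip(arma::dot(syn0.col(center), syn1.col(target)));
            double g = (label - f) * lr;
            errv += g * syn1.col(target);
            syn1.col(target) += g * syn0.col(center);
          }
          syn0.col(center) += errv;
        }
      }
    }
  }
  return syn0.t();  // V x dim
}
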