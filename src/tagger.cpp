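// BiLSTM-CRF sequence tagger.
//
// Architecture: word embedding (+ optional per-word character BiLSTM
// + capitalisation bit) -> inverted dropout -> token BiLSTM ->
// linear projection to per-tag emission scores -> linear-chain CRF
// with a hard BIO transition mask. Training minimises the CRF negative
// log-likelihood; all gradients are derived by hand and verified by
// finite differences in the test suite.
//
// All parameters live in one flat vector `theta`; the layout is fixed by
// make_dims() so R only ever sees an opaque numeric vector plus the dims
// list. Everything is deterministic given the seeds passed in.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double MASK_NEG = -1e4;  // additive penalty for illegal BIO transitions

struct Dims {
  int V, dw, Cv, dc, dch, H, L, D;
  size_t o_Ew, o_Ec, o_Wcf, o_bcf, o_Wcb, o_bcb,
         o_Wf, o_bf, o_Wb, o_bb, o_Wo, o_bo, o_A, total;
  bool use_char() const { return dc > 0; }
};

static Dims make_dims(const List& d) {
  Dims s;
  s.V  = as<int>(d["n_words"]);
  s.dw = as<int>(d["dim_word"]);
  s.Cv = as<int>(d["n_chars"]);
  s.dc = as<int>(d["dim_char"]);
  s.dch = as<int>(d["dim_char_hidden"]);
  s.H  = as<int>(d["hidden"]);
  s.L  = as<int>(d["n_tags"]);
  s.D  = s.dw + (s.dc > 0 ? 2 * s.dch : 0) + 1;
  size_t o = 0;
  s.o_Ew = o;  o += (size_t)s.V * s.dw;
  s.o_Ec = o;  o += (size_t)s.Cv * s.dc;
  size_t wc = (size_t)4 * s.dch * (s.dc + s.dch);
  s.o_Wcf = o; o += s.dc > 0 ? wc : 0;
  s.o_bcf = o; o += s.dc > 0 ? (size_t)4 * s.dch : 0;
  s.o_Wcb = o; o += s.dc > 0 ? wc : 0;
  s.o_bcb = o; o += s.dc > 0 ? (size_t)4 * s.dch : 0;
  s.o_Wf = o;  o += (size_t)4 * s.H * (s.D + s.H);
  s.o_bf = o;  o += (size_t)4 * s.H;
  s.o_Wb = o;  o += (size_t)4 * s.H * (s.D + s.H);
  s.o_bb = o;  o += (size_t)4 * s.H;
  s.o_Wo = o;  o += (size_t)s.L * 2 * s.H;
  s.o_bo = o;  o += (size_t)s.L;
  s.o_A  = o;  o += (size_t)(s.L + 2) * (s.L + 2);
  s.total = o;
  return s;
}

// Read-only / in-place views into the flat parameter vector.
struct Params {
  mat Ew, Ec, Wcf, Wcb, Wf, Wb, Wo, A;
  vec bcf, bcb, bf, bb, bo;
  Params(double* p, const Dims& s)
    : Ew(p + s.o_Ew, s.dw, s.V, false, true),
      Ec(s.dc > 0 ? mat(p + s.o_Ec, s.dc, s.Cv, false, true) : mat()),
      Wcf(s.dc > 0 ? mat(p + s.o_Wcf, 4 * s.dch, s.dc + s.dch, false, true) : mat()),
      Wcb(s.dc > 0 ? mat(p + s.o_Wcb, 4 * s.dch, s.dc + s.dch, false, true) : mat()),
      Wf(p + s.o_Wf, 4 * s.H, s.D + s.H, false, true),
      Wb(p + s.o_Wb, 4 * s.H, s.D + s.H, false, true),
      Wo(p + s.o_Wo, s.L, 2 * s.H, false, true),
      A(p + s.o_A, s.L + 2, s.L + 2, false, true),
      bcf(s.dc > 0 ? vec(p + s.o_bcf, 4 * s.dch, false, true) : vec()),
      bcb(s.dc > 0 ? vec(p + s.o_bcb, 4 * s.dch, false, true) : vec()),
      bf(p + s.o_bf, 4 * s.H, false, true),
      bb(p + s.o_bb, 4 * s.H, false, true),
      bo(p + s.o_bo, s.L, false, true) {}
};

static inline vec sigm(const vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// ---- LSTM (single direction) ----------------------------------------------
struct LSTMCache {
  mat X;    // Din x T inputs
  mat H;    // Hd x (T+1), col 0 = h_0 = 0
  mat C;    // Hd x (T+1)
  mat G;    // 4Hd x T, activated gates stacked [i; f; o; g]
};

static void lstm_forward(const mat& X, const mat& W, const vec& b, int Hd,
                         LSTMCache& cc) {
  const int T = X.n_cols;
  cc.X = X;
  cc.H.zeros(Hd, T + 1);
  cc.C.zeros(Hd, T + 1);
  cc.G.set_size(4 * Hd, T);
  for (int t = 0; t < T; ++t) {
    vec xh = arma::join_cols(X.col(t), cc.H.col(t));
    vec a = W * xh + b;
    vec i = sigm(a.subvec(0, Hd - 1));
    vec f = sigm(a.subvec(Hd, 2 * Hd - 1));
    vec o = sigm(a.subvec(2 * Hd, 3 * Hd - 1));
    vec g = arma::tanh(a.subvec(3 * Hd, 4 * Hd - 1));
    cc.C.col(t + 1) = f % cc.C.col(t) + i % g;
    cc.H.col(t + 1) = o % arma::tanh(cc.C.col(t + 1));
    cc.G.col(t).subvec(0, Hd - 1) = i;
    cc.G.col(t).subvec(Hd, 2 * Hd - 1) = f;
    cc.G.col(t).subvec(2 * Hd, 3 * Hd - 1) = o;
    cc.G.col(t).subvec(3 * Hd, 4 * Hd - 1) = g;
  }
}

// dH: Hd x T upstream gradient on hidden states. Accumulates dW, db and
// returns dX (Din x T).
static mat lstm_backward(const LSTMCache& cc, const mat& W, int Hd,
                         const mat& dH, mat& dW, vec& db) {
  const int T = cc.X.n_cols, Din = cc.X.n_rows;
  mat dX(Din, T, arma::fill::zeros);
  vec dh_next(Hd, arma::fill::zeros), dc_next(Hd, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    vec i = cc.G.col(t).subvec(0, Hd - 1);
    vec f = cc.G.col(t).subvec(Hd, 2 * Hd - 1);
    vec o = cc.G.col(t).subvec(2 * Hd, 3 * Hd - 1);
    vec g = cc.G.col(t).subvec(3 * Hd, 4 * Hd - 1);
    vec tc = arma::tanh(cc.C.col(t + 1));
    vec dh = dH.col(t) + dh_next;
    vec do_ = dh % tc;
    vec dc = dc_next + dh % o % (1.0 - tc % tc);
    vec di = dc % g;
    vec df = dc % cc.C.col(t);
    vec dg = dc % i;
    dc_next = dc % f;
    vec da(4 * Hd);
    da.subvec(0, Hd - 1)          = di % i % (1.0 - i);
    da.subvec(Hd, 2 * Hd - 1)     = df % f % (1.0 - f);
    da.subvec(2 * Hd, 3 * Hd - 1) = do_ % o % (1.0 - o);
    da.subvec(3 * Hd, 4 * Hd - 1) = dg % (1.0 - g % g);
    vec xh = arma::join_cols(cc.X.col(t), cc.H.col(t));
    dW += da * xh.t();
    db += da;
    vec dxh = W.t() * da;
    dX.col(t) = dxh.subvec(0, Din - 1);
    dh_next = dxh.subvec(Din, Din + Hd - 1);
  }
  return dX;
}

// ---- CRF -------------------------------------------------------------------
static double lse(const vec& x) {
  double m = x.max();
  return m + std::log(arma::sum(arma::exp(x - m)));
}

// NLL and gradient wrt emissions (T x L) and effective transitions.
// `gold` is 0-based. dA accumulates (same shape as A).
static double crf_nll_grad(const mat& E, const mat& Aeff, const arma::ivec& gold,
                           mat& dE, mat& dA) {
  const int T = E.n_rows, L = E.n_cols;
  const int START = L, STOP = L + 1;
  mat alpha(T, L), beta(T, L);
  for (int j = 0; j < L; ++j) alpha(0, j) = Aeff(START, j) + E(0, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < L; ++j)
      alpha(t, j) = lse(alpha.row(t - 1).t() + Aeff.submat(0, j, L - 1, j)) + E(t, j);
  for (int i = 0; i < L; ++i) beta(T - 1, i) = Aeff(i, STOP);
  for (int t = T - 2; t >= 0; --t)
    for (int i = 0; i < L; ++i) {
      vec v(L);
      for (int j = 0; j < L; ++j) v(j) = Aeff(i, j) + E(t + 1, j) + beta(t + 1, j);
      beta(t, i) = lse(v);
    }
  double logZ = lse(alpha.row(T - 1).t() + Aeff.submat(0, STOP, L - 1, STOP));

  double gold_score = Aeff(START, gold(0)) + E(0, gold(0));
  for (int t = 1; t < T; ++t) gold_score += Aeff(gold(t - 1), gold(t)) + E(t, gold(t));
  gold_score += Aeff(gold(T - 1), STOP);

  // emission marginals
  dE.set_size(T, L);
  for (int t = 0; t < T; ++t)
    for (int j = 0; j < L; ++j)
      dE(t, j) = std::exp(alpha(t, j) + beta(t, j) - logZ);
  for (int t = 0; t < T; ++t) dE(t, gold(t)) -= 1.0;

  // transition expected counts
  for (int j = 0; j < L; ++j)
    dA(START, j) += std::exp(Aeff(START, j) + E(0, j) + beta(0, j) - logZ);
  dA(START, gold(0)) -= 1.0;
  for (int t = 1; t < T; ++t) {
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j)
        dA(i, j) += std::exp(alpha(t - 1, i) + Aeff(i, j) + E(t, j) + beta(t, j) - logZ);
    dA(gold(t - 1), gold(t)) -= 1.0;
  }
  for (int i = 0; i < L; ++i)
    dA(i, STOP) += std::exp(alpha(T - 1, i) + Aeff(i, STOP) - logZ);
  dA(gold(T - 1), STOP) -= 1.0;

  return logZ - gold_score;
}

// ---- sequence forward: build inputs and emissions --------------------------
struct SeqCache {
  mat X;                    // D x T assembled inputs (post-dropout when training)
  mat Xraw;                 // D x T pre-dropout
  mat dropmask;             // D x T
  std::vector<LSTMCache> cf, cb;  // per-token char LSTMs (fwd over chars, bwd over reversed)
  LSTMCache fw, bw;         // token-level (bw runs over reversed input)
  mat Hcat;                 // 2H x T
  mat E;                    // T x L emissions
};

// seq: list(words = 0-based ivec, caps = numvec, chars = list of 0-based ivec)
static void seq_forward(const Params& P, const Dims& s, const List& seq,
                        SeqCache& cc, double dropout, std::mt19937* rng) {
  arma::ivec words = as<arma::ivec>(seq["words"]);
  vec caps = as<vec>(seq["caps"]);
  const int T = words.n_elem;
  cc.X.set_size(s.D, T);
  if (s.use_char()) { cc.cf.resize(T); cc.cb.resize(T); }
  List chl;
  if (s.use_char()) chl = as<List>(seq["chars"]);
  for (int t = 0; t < T; ++t) {
    cc.X.col(t).subvec(0, s.dw - 1) = P.Ew.col(words(t));
    if (s.use_char()) {
      arma::ivec ch = as<arma::ivec>(chl[t]);
      const int n = ch.n_elem;
      mat Xc(s.dc, n), Xcr(s.dc, n);
      for (int k = 0; k < n; ++k) {
        Xc.col(k) = P.Ec.col(ch(k));
        Xcr.col(k) = P.Ec.col(ch(n - 1 - k));
      }
      lstm_forward(Xc, P.Wcf, P.bcf, s.dch, cc.cf[t]);
      lstm_forward(Xcr, P.Wcb, P.bcb, s.dch, cc.cb[t]);
      cc.X.col(t).subvec(s.dw, s.dw + s.dch - 1) = cc.cf[t].H.col(n);
      cc.X.col(t).subvec(s.dw + s.dch, s.dw + 2 * s.dch - 1) = cc.cb[t].H.col(n);
    }
    cc.X(s.D - 1, t) = caps(t);
  }
  cc.Xraw = cc.X;
  if (dropout > 0 && rng != nullptr) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    cc.dropmask.set_size(s.D, T);
    const double keep = 1.0 - dropout;
    for (arma::uword i = 0; i < cc.dropmask.n_elem; ++i)
      cc.dropmask(i) = (unif(*rng) < keep) ? 1.0 / keep : 0.0;
    cc.X %= cc.dropmask;
  } else {
    cc.dropmask.reset();
  }
  lstm_forward(cc.X, P.Wf, P.bf, s.H, cc.fw);
  lstm_forward(arma::fliplr(cc.X), P.Wb, P.bb, s.H, cc.bw);
  cc.Hcat.set_size(2 * s.H, T);
  for (int t = 0; t < T; ++t) {
    cc.Hcat.col(t).subvec(0, s.H - 1) = cc.fw.H.col(t + 1);
    cc.Hcat.col(t).subvec(s.H, 2 * s.H - 1) = cc.bw.H.col(T - t);  // h for reversed pos
  }
  mat scores = P.Wo * cc.Hcat;             // L x T
  scores.each_col() += P.bo;
  cc.E = scores.t();                       // T x L
}

static void seq_backward(const Params& P, const Dims& s, const List& seq,
                         SeqCache& cc, const mat& dE, Params& G) {
  arma::ivec words = as<arma::ivec>(seq["words"]);
  const int T = words.n_elem;
  mat dScores = dE.t();                    // L x T
  G.Wo += dScores * cc.Hcat.t();
  G.bo += arma::sum(dScores, 1);
  mat dHcat = P.Wo.t() * dScores;          // 2H x T
  mat dHf = dHcat.rows(0, s.H - 1);
  mat dHb_nat = dHcat.rows(s.H, 2 * s.H - 1);
  mat dHb(s.H, T);
  for (int t = 0; t < T; ++t) dHb.col(t) = dHb_nat.col(T - 1 - t);
  mat dX = lstm_backward(cc.fw, P.Wf, s.H, dHf, G.Wf, G.bf);
  mat dXr = lstm_backward(cc.bw, P.Wb, s.H, dHb, G.Wb, G.bb);
  dX += arma::fliplr(dXr);
  if (cc.dropmask.n_elem > 0) dX %= cc.dropmask;
  List chl;
  if (s.use_char()) chl = as<List>(seq["chars"]);
  for (int t = 0; t < T; ++t) {
    G.Ew.col(words(t)) += dX.col(t).subvec(0, s.dw - 1);
    if (s.use_char()) {
      arma::ivec ch = as<arma::ivec>(chl[t]);
      const int n = ch.n_elem;
      mat dHc(s.dch, n, arma::fill::zeros);
      dHc.col(n - 1) = dX.col(t).subvec(s.dw, s.dw + s.dch - 1);
      mat dXc = lstm_backward(cc.cf[t], P.Wcf, s.dch, dHc, G.Wcf, G.bcf);
      dHc.zeros();
      dHc.col(n - 1) = dX.col(t).subvec(s.dw + s.dch, s.dw + 2 * s.dch - 1);
      mat dXcr = lstm_backward(cc.cb[t], P.Wcb, s.dch, dHc, G.Wcb, G.bcb);
      for (int k = 0; k < n; ++k) {
        G.Ec.col(ch(k)) += dXc.col(k);
        G.Ec.col(ch(n - 1 - k)) += dXcr.col(k);
      }
    }
  }
}

static mat effective_transitions(const Params& P, const mat& bio_mask) {
  return P.A + bio_mask * MASK_NEG;
}

// ---- exported entry points --------------------------------------------------

// [[Rcpp::export]]
double cpp_tagger_n_params(const List& dims) {
  return (double)make_dims(dims).total;
}

// Glorot-ish initialisation; deterministic given seed.
// [[Rcpp::export]]
NumericVector cpp_tagger_init(const List& dims, int seed) {
  Dims s = make_dims(dims);
  NumericVector theta((R_xlen_t)s.total);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  double* p = REAL(theta);
  for (size_t i = 0; i < s.total; ++i) p[i] = 0.0;
  Params P(p, s);
  auto fill_scaled = [&](mat& M) {
    double sc = std::sqrt(2.0 / (M.n_rows + M.n_cols));
    for (arma::uword i = 0; i < M.n_elem; ++i) M(i) = sc * norm(rng);
  };
  for (arma::uword i = 0; i < P.Ew.n_elem; ++i) P.Ew(i) = 0.1 * norm(rng);
  if (s.use_char()) {
    for (arma::uword i = 0; i < P.Ec.n_elem; ++i) P.Ec(i) = 0.1 * norm(rng);
    fill_scaled(P.Wcf); fill_scaled(P.Wcb);
    P.bcf.subvec(s.dch, 2 * s.dch - 1).fill(1.0);  // forget-gate bias
    P.bcb.subvec(s.dch, 2 * s.dch - 1).fill(1.0);
  }
  fill_scaled(P.Wf); fill_scaled(P.Wb);
  P.bf.subvec(s.H, 2 * s.H - 1).fill(1.0);
  P.bb.subvec(s.H, 2 * s.H - 1).fill(1.0);
  fill_scaled(P.Wo);
  for (arma::uword i = 0; i < P.A.n_elem; ++i) P.A(i) = 0.01 * norm(rng);
  return theta;
}

// Sum of per-sequence CRF NLL and its gradient over a batch.
// seqs[[i]] = list(words, caps, chars, tags (1-based)).
// [[Rcpp::export]]
List cpp_tagger_loss_grad(NumericVector theta, const List& dims, const List& seqs,
                          const arma::mat& bio_mask, double dropout, int seed) {
  Dims s = make_dims(dims);
  if ((size_t)theta.size() != s.total) stop("theta has wrong length");
  Params P(REAL(theta), s);
  NumericVector grad((R_xlen_t)s.total);
  Params G(REAL(grad), s);
  mat Aeff = effective_transitions(P, bio_mask);
  std::mt19937 rng((unsigned)seed);
  std::mt19937* rp = dropout > 0 ? &rng : nullptr;
  double loss = 0.0;
  mat dA(s.L + 2, s.L + 2, arma::fill::zeros);
  for (int i = 0; i < seqs.size(); ++i) {
    List seq = seqs[i];
    SeqCache cc;
    seq_forward(P, s, seq, cc, dropout, rp);
    arma::ivec gold = as<arma::ivec>(seq["tags"]) - 1;
    mat dE;
    loss += crf_nll_grad(cc.E, Aeff, gold, dE, dA);
    seq_backward(P, s, seq, cc, dE, G);
  }
  G.A += dA;
  // no gradient through masked (structurally forbidden) transitions
  for (arma::uword i = 0; i < G.A.n_elem; ++i)
    if (bio_mask(i) != 0.0) G.A(i) = 0.0;
  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// Loss only (no dropout): used for finite-difference gradient checks.
// [[Rcpp::export]]
double cpp_tagger_loss(NumericVector theta, const List& dims, const List& seqs,
                       const arma::mat& bio_mask) {
  Dims s = make_dims(dims);
  Params P(REAL(theta), s);
  mat Aeff = effective_transitions(P, bio_mask);
  double loss = 0.0;
  for (int i = 0; i < seqs.size(); ++i) {
    List seq = seqs[i];
    SeqCache cc;
    seq_forward(P, s, seq, cc, 0.0, nullptr);
    arma::ivec gold = as<arma::ivec>(seq["tags"]) - 1;
    mat dE, dA(s.L + 2, s.L + 2, arma::fill::zeros);
    loss += crf_nll_grad(cc.E, Aeff, gold, dE, dA);
  }
  return loss;
}

// Viterbi decode of one sequence; returns 1-based tag ids.
// [[Rcpp::export]]
IntegerVector cpp_tagger_decode(NumericVector theta, const List& dims, const List& seq,
                                const arma::mat& bio_mask) {
  Dims s = make_dims(dims);
  Params P(REAL(theta), s);
  SeqCache cc;
  seq_forward(P, s, seq, cc, 0.0, nullptr);
  mat Aeff = effective_transitions(P, bio_mask);
  // inline Viterbi (same tie-break as cpp_crf_viterbi)
  const int T = cc.E.n_rows, L = cc.E.n_cols, START = L, STOP = L + 1;
  mat delta(T, L);
  arma::imat psi(T, L);
  for (int j = 0; j < L; ++j) delta(0, j) = Aeff(START, j) + cc.E(0, j);
  for (int t = 1; t < T; ++t)
    for (int j = 0; j < L; ++j) {
      double best = -arma::datum::inf; int arg = 0;
      for (int i = 0; i < L; ++i) {
        double sc = delta(t - 1, i) + Aeff(i, j);
        if (sc > best) { best = sc; arg = i; }
      }
      delta(t, j) = best + cc.E(t, j);
      psi(t, j) = arg;
    }
  double best = -arma::datum::inf; int arg = 0;
  for (int j = 0; j < L; ++j) {
    double sc = delta(T - 1, j) + Aeff(j, STOP);
    if (sc > best) { best = sc; arg = j; }
  }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return path;
}
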