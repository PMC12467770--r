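#ifndef EXPRESSIVITY_NN_COMMON_H
#define EXPRESSIVITY_NN_COMMON_H

#include <RcppArmadillo.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>

// Deterministic PRNG (splitmix64) independent of R's RNG state, so that every
// stochastic step (init, shuffling, derangements, dropout) is keyed off one
// integer seed and reproduces bit-identically across platforms.
struct Splitmix {
  uint64_t state;
  explicit Splitmix(uint64_t seed) : state(seed) { next(); next(); }
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0, 1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double norm() {
    double u1 = unif(), u2 = unif();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2);
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
  void shuffle(arma::uvec &v) {
    for (int i = (int)v.n_elem - 1; i > 0; --i) {
      int j = below(i + 1);
      std::swap(v[i], v[j]);
    }
  }
  // fixed-point-free permutation: cyclic shift of a shuffled order
  arma::uvec derangement(int n) {
    arma::uvec p = arma::regspace<arma::uvec>(0, n - 1);
    shuffle(p);
    arma::uvec out(n);
    for (int k = 0; k < n; ++k) out[p[k]] = p[(k + 1) % n];
    return out;
  }
};

enum Act { ACT_ELU, ACT_RELU };

inline Act act_from_string(const std::string &s) {
  if (s == "elu") return ACT_ELU;
  if (s == "relu") return ACT_RELU;
  Rcpp::stop("unknown activation '%s' (use 'elu' or 'relu')", s.c_str());
}

inline arma::mat act_fwd(const arma::mat &z, Act a) {
  if (a == ACT_RELU) return arma::clamp(z, 0.0, arma::datum::inf);
  arma::mat out = z;
  out.for_each([](double &v) { if (v < 0.0) v = std::expm1(v); });
  return out;
}

// derivative expressed through z (pre-activation)
inline arma::mat act_deriv(const arma::mat &z, Act a) {
  arma::mat d = z;
  if (a == ACT_RELU) {
    d.for_each([](double &v) { v = (v > 0.0) ? 1.0 : 0.0; });
  } else {
    d.for_each([](double &v) { v = (v > 0.0) ? 1.0 : std::exp(v); });
  }
  return d;
}

// Fully connected network: sizes[0] -> ... -> sizes.back(), linear output.
struct Dense {
  std::vector<arma::mat> W;     // in x out
  std::vector<arma::rowvec> b;  // 1 x out
  Act act;

  void init_xavier(const std::vector<int> &sizes, Splitmix &rng) {
    int L = (int)sizes.size() - 1;
    W.resize(L);
    b.resize(L);
    for (int l = 0; l < L; ++l) {
      double lim = std::sqrt(6.0 / (sizes[l] + sizes[l + 1]));
      W[l].set_size(sizes[l], sizes[l + 1]);
      W[l].for_each([&](double &v) { v = (2.0 * rng.unif() - 1.0) * lim; });
      b[l] = arma::rowvec(sizes[l + 1], arma::fill::zeros);
    }
  }

  // plain forward, no cache
  arma::vec forward(const arma::mat &X) const {
    arma::mat h = X;
    int L = (int)W.size();
    for (int l = 0; l < L; ++l) {
      h = h * W[l];
      h.each_row() += b[l];
      if (l < L - 1) h = act_fwd(h, act);
    }
    return h.col(0);
  }

  // forward caching pre-activations; hidden[l] = activated output of layer l
  arma::vec forward_cached(const arma::mat &X, std::vector<arma::mat> &zs,
                           std::vector<arma::mat> &as) const {
    int L = (int)W.size();
    zs.resize(L);
    as.resize(L);
    arma::mat h = X;
    for (int l = 0; l < L; ++l) {
      zs[l] = h * W[l];
      zs[l].each_row() += b[l];
      h = (l < L - 1) ? act_fwd(zs[l], act) : zs[l];
      as[l] = h;
    }
    return h.col(0);
  }

  // backprop for scalar-output net. dout: batch x 1 gradient wrt output.
  // Accumulates into gW/gb (must be pre-sized and zeroed or valid).
  void backward(const arma::mat &X, const std::vector<arma::mat> &zs,
                const std::vector<arma::mat> &as, const arma::vec &dout,
                std::vector<arma::mat> &gW, std::vector<arma::rowvec> &gb) const {
    int L = (int)W.size();
    arma::mat delta = dout;  // batch x 1
    for (int l = L - 1; l >= 0; --l) {
      const arma::mat &input = (l == 0) ? X : as[l - 1];
      gW[l] += input.t() * delta;
      gb[l] += arma::sum(delta, 0);
      if (l > 0) {
        delta = (delta * W[l].t()) % act_deriv(zs[l - 1], act);
      }
    }
  }
};

struct AdamState {
  std::vector<arma::mat> mW, vW;
  std::vector<arma::rowvec> mb, vb;
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;

  void init(const Dense &net) {
    size_t L = net.W.size();
    mW.resize(L); vW.resize(L); mb.resize(L); vb.resize(L);
    for (size_t l = 0; l < L; ++l) {
      mW[l] = arma::zeros(net.W[l].n_rows, net.W[l].n_cols);
      vW[l] = mW[l];
      mb[l] = arma::zeros<arma::rowvec>(net.b[l].n_elem);
      vb[l] = mb[l];
    }
  }

  void step(Dense &net, const std::vector<arma::mat> &gW,
            const std::vector<arma::rowvec> &gb, double lr) {
    ++t;
    double c1 = 1.0 - std::pow(beta1, (double)t);
    double c2 = 1.0 - std::pow(beta2, (double)t);
    for (size_t l = 0; l < net.W.size(); ++l) {
      mW[l] = beta1 * mW[l] + (1 - beta1) * gW[l];
      vW[l] = beta2 * vW[l] + (1 - beta2) * arma::square(gW[l]);
      net.W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
      mb[l] = beta1 * mb[l] + (1 - beta1) * gb[l];
      vb[l] = beta2 * vb[l] + (1 - beta2) * arma::square(gb[l]);
      net.b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }
};

inline double log_mean_exp(const arma::vec &x) {
  double m = x.max();
  return m + std::log(arma::mean(arma::exp(x - m)));
}

// log(a + b) from log a, log b
inline double log_add_exp(double la, double lb) {
  double m = std::max(la, lb);
  return m + std::log(std::exp(la - m) + std::exp(lb - m));
}

// Mann-Whitney AUROC with midrank tie handling (half credit for ties)
inline double auroc_rank(const arma::vec &scores, const arma::vec &labels) {
  int n = (int)scores.n_elem;
  arma::uvec ord = arma::stable_sort_index(scores);
  arma::vec ranks(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && scores[ord[j + 1]] == scores[ord[i]]) ++j;
    double r = 0.5 * ((i + 1) + (j + 1));
    for (int k = i; k <= j; ++k) ranks[ord[k]] = r;
    i = j + 1;
  }
  double npos = arma::accu(labels), nneg = n - npos;
  if (npos == 0 || nneg == 0) return NA_REAL;
  double rpos = arma::dot(ranks, labels);
  return (rpos - npos * (npos + 1) / 2.0) / (npos * nneg);
}

// R list <-> Dense weight conversion
inline Rcpp::List dense_to_list(const Dense &net) {
  Rcpp::List Ws(net.W.size()), bs(net.b.size());
  for (size_t l = 0; l < net.W.size(); ++l) {
    Ws[l] = net.W[l];
    bs[l] = arma::rowvec(net.b[l]);
  }
  return Rcpp::List::create(Rcpp::Named("W") = Ws, Rcpp::Named("b") = bs);
}

inline Dense dense_from_list(const Rcpp::List &lst, Act act) {
  Dense net;
  net.act = act;
  Rcpp::List Ws = lst["W"], bs = lst["b"];
  net.W.resize(Ws.size());
  net.b.resize(bs.size());
  for (int l = 0; l < Ws.size(); ++l) {
    net.W[l] = Rcpp::as<arma::mat>(Ws[l]);
    net.b[l] = Rcpp::as<arma::rowvec>(bs[l]);
  }
  return net;
}

#endif
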