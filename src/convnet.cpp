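// [[Rcpp::depends(RcppArmadillo)]]
#include "nn_common.h"
using namespace Rcpp;

// Small convolutional backbone: a stack of 3x3 stride-2 convolutions (pad 1,
// ReLU), global average pooling, and a fully connected head with dropout.
// Images arrive as grayscale rows in [0,1]; they are replicated to three
// channels and normalized with ImageNet statistics before the stem.

static const double IMNET_MEAN[3] = {0.485, 0.456, 0.406};
static const double IMNET_SD[3] = {0.229, 0.224, 0.225};

struct ConvLayer {
  arma::mat W;      // (9*Cin) x Cout
  arma::rowvec b;   // 1 x Cout
};

// k=3, pad=1; row ordering r = ho + wo*Ho matches arma cube memory layout
static arma::mat im2col3(const arma::cube &x, int stride, int Ho, int Wo) {
  int H = (int)x.n_rows, W = (int)x.n_cols, C = (int)x.n_slices;
  arma::mat col(Ho * Wo, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        int cc = c * 9 + kj * 3 + ki;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - 1;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - 1;
            if (hi < 0 || hi >= H) continue;
            col(ho + wo * Ho, cc) = x(hi, wi, c);
          }
        }
      }
  return col;
}

static void col2im3_add(const arma::mat &dcol, arma::cube &dx, int stride,
                        int Ho, int Wo) {
  int H = (int)dx.n_rows, W = (int)dx.n_cols, C = (int)dx.n_slices;
  for (int c = 0; c < C; ++c)
    for (int kj = 0; kj < 3; ++kj)
      for (int ki = 0; ki < 3; ++ki) {
        int cc = c * 9 + kj * 3 + ki;
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride + kj - 1;
          if (wi < 0 || wi >= W) continue;
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride + ki - 1;
            if (hi < 0 || hi >= H) continue;
            dx(hi, wi, c) += dcol(ho + wo * Ho, cc);
          }
        }
      }
}

static arma::cube make_input(const arma::rowvec &gray, int S) {
  arma::cube x(S, S, 3);
  arma::mat g(gray.memptr(), S, S);  // column-major S x S
  for (int c = 0; c < 3; ++c) x.slice(c) = (g - IMNET_MEAN[c]) / IMNET_SD[c];
  return x;
}

struct ConvCache {
  std::vector<arma::mat> cols;      // per layer im2col of its input
  std::vector<arma::mat> preact;    // per layer pre-activation (HoWo x Cout)
  std::vector<int> Ho, Wo;
};

// forward through conv stack; returns per-layer pooled vectors; fills cache
static std::vector<arma::rowvec> conv_forward(const arma::cube &x0,
                                              const std::vector<ConvLayer> &layers,
                                              ConvCache *cache) {
  std::vector<arma::rowvec> pooled(layers.size());
  arma::cube cur = x0;
  for (size_t l = 0; l < layers.size(); ++l) {
    int H = (int)cur.n_rows, W = (int)cur.n_cols;
    int Ho = (H + 2 - 3) / 2 + 1, Wo = (W + 2 - 3) / 2 + 1;
    arma::mat col = im2col3(cur, 2, Ho, Wo);
    arma::mat z = col * layers[l].W;
    z.each_row() += layers[l].b;
    arma::mat a = arma::clamp(z, 0.0, arma::datum::inf);
    pooled[l] = arma::mean(a, 0);
    if (cache) {
      cache->cols.push_back(std::move(col));
      cache->preact.push_back(z);
      cache->Ho.push_back(Ho);
      cache->Wo.push_back(Wo);
    }
    cur = arma::cube(a.memptr(), Ho, Wo, a.n_cols);
  }
  return pooled;
}

// backward through conv stack given gradient wrt last layer's pooled vector
static void conv_backward(const std::vector<ConvLayer> &layers,
                          const ConvCache &cache, const arma::rowvec &dpool,
                          std::vector<arma::mat> &gW,
                          std::vector<arma::rowvec> &gb) {
  int L = (int)layers.size();
  int Ho = cache.Ho[L - 1], Wo = cache.Wo[L - 1];
  arma::mat dout(Ho * Wo, dpool.n_elem);
  dout.each_row() = dpool / (double)(Ho * Wo);
  for (int l = L - 1; l >= 0; --l) {
    // mask ReLU
    arma::mat dz = dout % arma::conv_to<arma::mat>::from(cache.preact[l] > 0.0);
    gW[l] += cache.cols[l].t() * dz;
    gb[l] += arma::sum(dz, 0);
    if (l > 0) {
      arma::mat dcol = dz * layers[l].W.t();
      int Hi = cache.Ho[l - 1], Wi = cache.Wo[l - 1];
      int Ci = (int)layers[l - 1].W.n_cols;
      arma::cube dx(Hi, Wi, Ci, arma::fill::zeros);
      col2im3_add(dcol, dx, 2, cache.Ho[l], cache.Wo[l]);
      dout = arma::mat(dx.memptr(), Hi * Wi, Ci);
    }
  }
}

static List conv_layers_to_list(const std::vector<ConvLayer> &layers) {
  List Ws(layers.size()), bs(layers.size());
  for (size_t l = 0; l < layers.size(); ++l) {
    Ws[l] = layers[l].W;
    bs[l] = arma::rowvec(layers[l].b);
  }
  return List::create(Named("W") = Ws, Named("b") = bs);
}

static std::vector<ConvLayer> conv_layers_from_list(const List &lst) {
  List Ws = lst["W"], bs = lst["b"];
  std::vector<ConvLayer> layers(Ws.size());
  for (int l = 0; l < Ws.size(); ++l) {
    layers[l].W = as<arma::mat>(Ws[l]);
    layers[l].b = as<arma::rowvec>(bs[l]);
  }
  return layers;
}

static std::vector<ConvLayer> conv_init(int in_ch, const IntegerVector &widths,
                                        Splitmix &rng) {
  std::vector<ConvLayer> layers(widths.size());
  int cin = in_ch;
  for (int l = 0; l < widths.size(); ++l) {
    int cout = widths[l];
    double lim = std::sqrt(6.0 / (9.0 * cin + 9.0 * cout));  // Xavier over fans
    layers[l].W.set_size(9 * cin, cout);
    layers[l].W.for_each([&](double &v) { v = (2.0 * rng.unif() - 1.0) * lim; });
    layers[l].b = arma::rowvec(cout, arma::fill::zeros);
    cin = cout;
  }
  return layers;
}

// [[Rcpp::export]]
List convnet_init_cpp(const IntegerVector &widths, const IntegerVector &head_hidden,
                      double seed) {
  Splitmix rng((uint64_t)seed);
  std::vector<ConvLayer> conv = conv_init(3, widths, rng);
  std::vector<int> hsizes;
  hsizes.push_back(widths[widths.size() - 1]);
  for (int h : head_hidden) hsizes.push_back(h);
  hsizes.push_back(1);
  Dense head;
  head.act = ACT_RELU;
  head.init_xavier(hsizes, rng);
  return List::create(Named("conv") = conv_layers_to_list(conv),
                      Named("head") = dense_to_list(head));
}

// Evaluation-mode forward pass (dropout off): pooled features at every conv
// layer, the head's hidden activations, and logits.
// [[Rcpp::export]]
List convnet_forward_cpp(const arma::mat &imgs, int input_size,
                         const List &weights) {
  std::vector<ConvLayer> conv = conv_layers_from_list(weights["conv"]);
  Dense head = dense_from_list(weights["head"], ACT_RELU);
  int n = (int)imgs.n_rows;
  int L = (int)conv.size();
  std::vector<arma::mat> pooled(L);
  for (int l = 0; l < L; ++l) pooled[l].set_size(n, conv[l].W.n_cols);
  for (int i = 0; i < n; ++i) {
    arma::cube x0 = make_input(imgs.row(i), input_size);
    std::vector<arma::rowvec> p = conv_forward(x0, conv, nullptr);
    for (int l = 0; l < L; ++l) pooled[l].row(i) = p[l];
  }
  std::vector<arma::mat> zs, as;
  arma::vec logits = head.forward_cached(pooled[L - 1], zs, as);
  int HL = (int)head.W.size();
  arma::mat prelogit = (HL >= 2) ? as[HL - 2] : pooled[L - 1];
  List pooled_out(L);
  for (int l = 0; l < L; ++l) pooled_out[l] = pooled[l];
  return List::create(Named("pooled") = pooled_out,
                      Named("prelogit") = prelogit,
                      Named("logits") = logits);
}

// End-to-end training with BCE loss, Adam (+ L2 weight decay), dropout in the
// head only, best checkpoint by validation AUROC.
// [[Rcpp::export]]
List convnet_train_cpp(const arma::mat &imgs, const arma::vec &y,
                       const arma::mat &imgs_val, const arma::vec &yval,
                       int input_size, const IntegerVector &widths,
                       const IntegerVector &head_hidden, double dropout,
                       double lr, double weight_decay, int batch_size,
                       int epochs, double seed, const List &init_weights) {
  int n = (int)imgs.n_rows;
  Splitmix rng((uint64_t)seed);
  std::vector<ConvLayer> conv;
  Dense head;
  head.act = ACT_RELU;
  if (init_weights.size() > 0) {
    conv = conv_layers_from_list(init_weights["conv"]);
    head = dense_from_list(init_weights["head"], ACT_RELU);
  } else {
    conv = conv_init(3, widths, rng);
    std::vector<int> hsizes;
    hsizes.push_back(widths[widths.size() - 1]);
    for (int h : head_hidden) hsizes.push_back(h);
    hsizes.push_back(1);
    head.init_xavier(hsizes, rng);
  }
  int L = (int)conv.size();
  int HL = (int)head.W.size();

  // Adam state over all parameters
  std::vector<arma::mat> gcW(L), mcW(L), vcW(L);
  std::vector<arma::rowvec> gcb(L), mcb(L), vcb(L);
  for (int l = 0; l < L; ++l) {
    mcW[l] = arma::zeros(conv[l].W.n_rows, conv[l].W.n_cols);
    vcW[l] = mcW[l];
    mcb[l] = arma::zeros<arma::rowvec>(conv[l].b.n_elem);
    vcb[l] = mcb[l];
  }
  std::vector<arma::mat> ghW(HL), mhW(HL), vhW(HL);
  std::vector<arma::rowvec> ghb(HL), mhb(HL), vhb(HL);
  for (int l = 0; l < HL; ++l) {
    mhW[l] = arma::zeros(head.W[l].n_rows, head.W[l].n_cols);
    vhW[l] = mhW[l];
    mhb[l] = arma::zeros<arma::rowvec>(head.b[l].n_elem);
    vhb[l] = mhb[l];
  }
  double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long t = 0;
  auto adam_update = [&](arma::mat &w, arma::mat &m, arma::mat &v,
                         const arma::mat &g, double c1, double c2) {
    m = beta1 * m + (1 - beta1) * g;
    v = beta2 * v + (1 - beta2) * arma::square(g);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  };
  auto adam_update_r = [&](arma::rowvec &w, arma::rowvec &m, arma::rowvec &v,
                           const arma::rowvec &g, double c1, double c2) {
    m = beta1 * m + (1 - beta1) * g;
    v = beta2 * v + (1 - beta2) * arma::square(g);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + eps);
  };

  int n_batches = std::max(1, n / batch_size);
  std::vector<double> loss_hist, auc_hist;
  double best_auc = -1.0;
  List best_weights = List::create(Named("conv") = conv_layers_to_list(conv),
                                   Named("head") = dense_to_list(head));
  int best_epoch = 0;

  int Clast = (int)conv[L - 1].W.n_cols;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    arma::uvec perm = arma::regspace<arma::uvec>(0, n - 1);
    rng.shuffle(perm);
    double epoch_loss = 0.0;
    long n_seen = 0;
    for (int bi = 0; bi < n_batches; ++bi) {
      int lo = bi * batch_size;
      int hi = std::min(n, lo + batch_size) - 1;
      arma::uvec idx = perm.subvec(lo, hi);
      int b = (int)idx.n_elem;

      std::vector<ConvCache> caches(b);
      arma::mat feats(b, Clast);
      for (int k = 0; k < b; ++k) {
        arma::cube x0 = make_input(imgs.row(idx[k]), input_size);
        std::vector<arma::rowvec> p = conv_forward(x0, conv, &caches[k]);
        feats.row(k) = p[L - 1];
      }

      // head forward with dropout
      std::vector<arma::mat> zs(HL), as(HL), masks(HL);
      arma::mat h = feats;
      for (int l = 0; l < HL; ++l) {
        zs[l] = h * head.W[l];
        zs[l].each_row() += head.b[l];
        if (l < HL - 1) {
          h = arma::clamp(zs[l], 0.0, arma::datum::inf);
          if (dropout > 0.0) {
            masks[l] = h;
            masks[l].for_each([&](double &v) {
              v = (rng.unif() < dropout) ? 0.0 : 1.0 / (1.0 - dropout);
            });
            h %= masks[l];
          }
          as[l] = h;
        } else {
          as[l] = zs[l];
        }
      }
      arma::vec logits = as[HL - 1].col(0);
      arma::vec yb = y.elem(idx);
      arma::vec p = 1.0 / (1.0 + arma::exp(-logits));
      for (int k = 0; k < b; ++k) {
        double z = logits[k];
        double sp = (z > 0) ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
        epoch_loss += sp - yb[k] * z;
      }
      n_seen += b;

      // zero grads
      for (int l = 0; l < L; ++l) {
        gcW[l] = arma::zeros(conv[l].W.n_rows, conv[l].W.n_cols);
        gcb[l] = arma::zeros<arma::rowvec>(conv[l].b.n_elem);
      }
      for (int l = 0; l < HL; ++l) {
        ghW[l] = arma::zeros(head.W[l].n_rows, head.W[l].n_cols);
        ghb[l] = arma::zeros<arma::rowvec>(head.b[l].n_elem);
      }

      // head backward, propagating to the pooled features
      arma::mat delta = arma::mat(p - yb);
      delta /= (double)b;
      for (int l = HL - 1; l >= 0; --l) {
        const arma::mat &input = (l == 0) ? feats : as[l - 1];
        ghW[l] += input.t() * delta;
        ghb[l] += arma::sum(delta, 0);
        delta = delta * head.W[l].t();
        if (l > 0) {
          if (dropout > 0.0) delta %= masks[l - 1];
          delta %= arma::conv_to<arma::mat>::from(zs[l - 1] > 0.0);
        }
      }
      arma::mat dfeats = delta;  // b x Clast

      for (int k = 0; k < b; ++k)
        conv_backward(conv, caches[k], dfeats.row(k), gcW, gcb);

      if (weight_decay > 0.0) {
        for (int l = 0; l < L; ++l) gcW[l] += weight_decay * conv[l].W;
        for (int l = 0; l < HL; ++l) ghW[l] += weight_decay * head.W[l];
      }

      ++t;
      double c1 = 1.0 - std::pow(beta1, (double)t);
      double c2 = 1.0 - std::pow(beta2, (double)t);
      for (int l = 0; l < L; ++l) {
        adam_update(conv[l].W, mcW[l], vcW[l], gcW[l], c1, c2);
        adam_update_r(conv[l].b, mcb[l], vcb[l], gcb[l], c1, c2);
      }
      for (int l = 0; l < HL; ++l) {
        adam_update(head.W[l], mhW[l], vhW[l], ghW[l], c1, c2);
        adam_update_r(head.b[l], mhb[l], vhb[l], ghb[l], c1, c2);
      }
      Rcpp::checkUserInterrupt();
    }
    loss_hist.push_back(epoch_loss / n_seen);

    // validation AUROC (eval mode)
    int nv = (int)imgs_val.n_rows;
    arma::mat vfeats(nv, Clast);
    for (int i = 0; i < nv; ++i) {
      arma::cube x0 = make_input(imgs_val.row(i), input_size);
      std::vector<arma::rowvec> p = conv_forward(x0, conv, nullptr);
      vfeats.row(i) = p[L - 1];
    }
    arma::vec vlogits = head.forward(vfeats);
    double auc = auroc_rank(vlogits, yval);
    auc_hist.push_back(auc);
    if (auc > best_auc) {
      best_auc = auc;
      best_weights = List::create(Named("conv") = conv_layers_to_list(conv),
                                  Named("head") = dense_to_list(head));
      best_epoch = epoch + 1;
    }
  }

  return List::create(Named("weights") = best_weights,
                      Named("loss") = loss_hist,
                      Named("val_auroc") = auc_hist,
                      Named("best_epoch") = best_epoch,
                      Named("best_val_auroc") = best_auc);
}
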