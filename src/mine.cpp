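// [[Rcpp::depends(RcppArmadillo)]]
#include "nn_common.h"
using namespace Rcpp;

// Score a batch of (feature, attribute) pairs with a statistics network.
// X: n x (d+1) matrix of concatenated [f | a] rows.
// [[Rcpp::export]]
arma::vec mlp_score_cpp(const arma::mat &X, const List &weights,
                        const std::string &activation) {
  Dense net = dense_from_list(weights, act_from_string(activation));
  return net.forward(X);
}

// Train the MINE statistics network by mini-batch gradient ascent on the
// Donsker-Varadhan bound. The gradient's log-term denominator uses an
// exponential moving average of the mean of exp(marginal scores), held in log
// space for numerical stability; reported bounds always use the raw term.
//
// F: n x d (already standardized upstream if requested), A: length n.
// Returns best-epoch weights, full-data bound history, and the final bound
// recomputed on the full dataset with a fresh derangement.
// [[Rcpp::export]]
List mine_train_cpp(const arma::mat &F, const arma::vec &A,
                    const IntegerVector &hidden, const std::string &activation,
                    double lr, int batch_size, int max_epochs,
                    double ema_decay, int patience, double val_fraction,
                    double seed) {
  const int n = (int)F.n_rows;
  const int d = (int)F.n_cols;
  Act act = act_from_string(activation);
  Splitmix rng((uint64_t)seed);

  // internal monitoring split: plateau detection and checkpoint selection use
  // held-out pairs so the stopping signal is not inflated by overfitting;
  // val_fraction = 0 monitors the training data itself
  arma::uvec all_idx = arma::regspace<arma::uvec>(0, n - 1);
  rng.shuffle(all_idx);
  int n_val = (int)std::floor(val_fraction * n);
  if (n_val > 0 && n_val < 2) n_val = 2;
  int n_tr = n - n_val;
  arma::uvec tr_idx = all_idx.subvec(0, n_tr - 1);
  arma::uvec val_idx = (n_val > 0) ? all_idx.subvec(n_tr, n - 1) : tr_idx;
  int n_mon = (int)val_idx.n_elem;

  std::vector<int> sizes;
  sizes.push_back(d + 1);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(1);

  Dense net;
  net.act = act;
  net.init_xavier(sizes, rng);
  AdamState adam;
  adam.init(net);

  const int L = (int)net.W.size();
  std::vector<arma::mat> gW(L);
  std::vector<arma::rowvec> gb(L);

  // joint and marginal batches stacked into one matrix: rows [0, b) are the
  // matched pairs, rows [b, 2b) the deranged ones — one gemm pass for both
  arma::mat XB(2 * batch_size, d + 1);
  std::vector<arma::mat> zsB, asB;

  double log_ema = 0.0;
  bool ema_init = false;
  const double log_decay = std::log(ema_decay);
  const double log_1mdecay = std::log1p(-ema_decay);

  arma::mat Xfull(n, d + 1);
  Xfull.cols(0, d - 1) = F;
  Xfull.col(d) = A;

  // DV bound on the rows `rows` of the dataset, fresh derangement
  auto bound_on = [&](const arma::uvec &rows) {
    int m = (int)rows.n_elem;
    arma::mat X2(2 * m, d + 1);
    X2.rows(0, m - 1) = Xfull.rows(rows);
    X2.rows(m, 2 * m - 1) = X2.rows(0, m - 1);
    arma::vec Asub = A.elem(rows);
    X2.col(d).subvec(m, 2 * m - 1) = Asub.elem(rng.derangement(m));
    arma::vec t = net.forward(X2);
    return arma::mean(t.subvec(0, m - 1)) -
           log_mean_exp(t.subvec(m, 2 * m - 1));
  };

  std::vector<double> history;
  double best_bound = -arma::datum::inf;
  Dense best_net = net;
  int since_improve = 0;
  int n_batches = n_tr / batch_size;
  if (n_batches < 1)
    Rcpp::stop("training split smaller than batch_size; lower batch_size or val_fraction");
  int epochs_run = 0;

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    arma::uvec perm = tr_idx;
    rng.shuffle(perm);
    for (int bi = 0; bi < n_batches; ++bi) {
      arma::uvec idx = perm.subvec(bi * batch_size, (bi + 1) * batch_size - 1);
      arma::uvec der = rng.derangement(batch_size);
      for (int k = 0; k < batch_size; ++k) {
        for (int j = 0; j < d; ++j) {
          XB(k, j) = F(idx[k], j);
          XB(batch_size + k, j) = F(idx[k], j);
        }
        XB(k, d) = A(idx[k]);
        XB(batch_size + k, d) = A(idx[der[k]]);
      }
      arma::vec t = net.forward_cached(XB, zsB, asB);
      arma::vec tm = t.subvec(batch_size, 2 * batch_size - 1);

      double lme = log_mean_exp(tm);  // log of batch mean of exp scores
      if (!ema_init) {
        log_ema = lme;
        ema_init = true;
      } else {
        log_ema = log_add_exp(log_decay + log_ema, log_1mdecay + lme);
      }

      // minimize -(DV); d(-DV)/dT_joint = -1/b ; d/dT_marg_i = exp(t_i)/(b*ema)
      arma::vec dout(2 * batch_size);
      dout.subvec(0, batch_size - 1).fill(-1.0 / batch_size);
      dout.subvec(batch_size, 2 * batch_size - 1) =
          arma::exp(tm - log_ema) / batch_size;

      for (int l = 0; l < L; ++l) {
        gW[l] = arma::zeros(net.W[l].n_rows, net.W[l].n_cols);
        gb[l] = arma::zeros<arma::rowvec>(net.b[l].n_elem);
      }
      net.backward(XB, zsB, asB, dout, gW, gb);
      adam.step(net, gW, gb, lr);
    }

    double bound = bound_on(val_idx);
    history.push_back(bound);
    epochs_run = epoch + 1;
    if (bound > best_bound) {
      best_bound = bound;
      best_net = net;
      since_improve = 0;
    } else {
      ++since_improve;
    }
    if (since_improve >= patience) break;
    (void)n_mon;
  }

  // final bound: full data, fresh derangement, selected network
  net = best_net;
  double final_bound = bound_on(all_idx);

  return List::create(
      Named("weights") = dense_to_list(best_net),
      Named("final_bound") = final_bound,
      Named("bound_history") = history,
      Named("epochs_run") = epochs_run,
      Named("ema_state") = std::exp(log_ema));
}

// Train a fully connected classification head with binary cross-entropy,
// inverted dropout on hidden layers, optional warmup+cosine learning-rate
// schedule, and best-checkpoint selection by validation AUROC.
// X: n x d feature matrix; y in {0,1}.
// [[Rcpp::export]]
List dense_bce_train_cpp(const arma::mat &X, const arma::vec &y,
                         const arma::mat &Xval, const arma::vec &yval,
                         const IntegerVector &hidden,
                         const std::string &activation, double dropout,
                         double lr, double weight_decay, int batch_size,
                         int epochs, const std::string &schedule, double seed) {
  const int n = (int)X.n_rows;
  const int d = (int)X.n_cols;
  Act act = act_from_string(activation);
  Splitmix rng((uint64_t)seed);

  std::vector<int> sizes;
  sizes.push_back(d);
  for (int h : hidden) sizes.push_back(h);
  sizes.push_back(1);

  Dense net;
  net.act = act;
  net.init_xavier(sizes, rng);
  AdamState adam;
  adam.init(net);

  const int L = (int)net.W.size();
  std::vector<arma::mat> gW(L);
  std::vector<arma::rowvec> gb(L);
  std::vector<arma::mat> zs, as;

  int n_batches = std::max(1, n / batch_size);
  long total_steps = (long)n_batches * epochs;
  long warmup_steps = std::max(1L, total_steps / 10);
  long step = 0;

  std::vector<double> loss_hist, auc_hist;
  double best_auc = -1.0;
  Dense best_net = net;
  int best_epoch = 0;

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
      arma::mat Xb = X.rows(idx);
      arma::vec yb = y.elem(idx);

      double cur_lr = lr;
      if (schedule == "warmup_cosine") {
        if (step < warmup_steps) {
          cur_lr = lr * (double)(step + 1) / (double)warmup_steps;
        } else {
          double frac = (double)(step - warmup_steps) /
                        std::max(1.0, (double)(total_steps - warmup_steps));
          cur_lr = lr * 0.5 * (1.0 + std::cos(M_PI * frac));
        }
      }
      ++step;

      // forward with inverted dropout on hidden activations
      zs.resize(L);
      as.resize(L);
      std::vector<arma::mat> masks(L);
      arma::mat h = Xb;
      for (int l = 0; l < L; ++l) {
        zs[l] = h * net.W[l];
        zs[l].each_row() += net.b[l];
        if (l < L - 1) {
          h = act_fwd(zs[l], act);
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
      arma::vec logits = as[L - 1].col(0);
      arma::vec p = 1.0 / (1.0 + arma::exp(-logits));
      // BCE loss (mean over batch), stable via softplus
      for (int k = 0; k < b; ++k) {
        double z = logits[k];
        double sp = (z > 0) ? z + std::log1p(std::exp(-z)) : std::log1p(std::exp(z));
        epoch_loss += sp - yb[k] * z;
      }
      n_seen += b;

      arma::vec dout = (p - yb) / b;
      for (int l = 0; l < L; ++l) {
        gW[l] = arma::zeros(net.W[l].n_rows, net.W[l].n_cols);
        gb[l] = arma::zeros<arma::rowvec>(net.b[l].n_elem);
      }
      // backward honoring dropout masks
      arma::mat delta = dout;
      for (int l = L - 1; l >= 0; --l) {
        const arma::mat &input = (l == 0) ? Xb : as[l - 1];
        gW[l] += input.t() * delta;
        gb[l] += arma::sum(delta, 0);
        if (l > 0) {
          delta = (delta * net.W[l].t());
          if (dropout > 0.0) delta %= masks[l - 1];
          delta %= act_deriv(zs[l - 1], act);
        }
      }
      if (weight_decay > 0.0)
        for (int l = 0; l < L; ++l) gW[l] += weight_decay * net.W[l];
      adam.step(net, gW, gb, cur_lr);
    }
    loss_hist.push_back(epoch_loss / n_seen);

    arma::vec val_logits = net.forward(Xval);
    double auc = auroc_rank(val_logits, yval);
    auc_hist.push_back(auc);
    if (auc > best_auc) {
      best_auc = auc;
      best_net = net;
      best_epoch = epoch + 1;
    }
  }

  return List::create(Named("weights") = dense_to_list(best_net),
                      Named("final_weights") = dense_to_list(net),
                      Named("loss") = loss_hist,
                      Named("val_auroc") = auc_hist,
                      Named("best_epoch") = best_epoch,
                      Named("best_val_auroc") = best_auc);
}

// Xavier-initialized dense weights without training (deterministic given seed).
// [[Rcpp::export]]
List dense_init_cpp(const IntegerVector &sizes, double seed) {
  Splitmix rng((uint64_t)seed);
  std::vector<int> sz(sizes.begin(), sizes.end());
  Dense net;
  net.act = ACT_RELU;
  net.init_xavier(sz, rng);
  return dense_to_list(net);
}
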