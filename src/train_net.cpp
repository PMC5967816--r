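// ADAM training loop for the fully connected softmax classifier network.
// Layers: Z = W*A + b, optional batch normalization (code bn=1), then
// activation (act: 0 identity, 1 ReLU, 2 sigmoid); softmax cross-entropy
// on the two output units. Batching, shuffling and batch top-up use an
// internal xorshift RNG so a fixed seed reproduces the loss curve exactly;
// weight initializations come from R (one set per permitted restart).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL) {}
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  // uniform integer in [0, n)
  arma::uword below(arma::uword n) { return (arma::uword)(next() % n); }
};

struct Layer {
  arma::mat W, mW, vW;
  arma::vec b, mb, vb;
  int act;      // 0 identity, 1 relu, 2 sigmoid
  bool bn;
  arma::vec gamma, beta, mg, vg, mbe, vbe;
  arma::vec run_mean, run_var;
  bool run_init;
};

const double BN_EPS = 1e-5;
const double BN_MOMENTUM = 0.9;

arma::mat activate(const arma::mat& Z, int act) {
  switch (act) {
    case 1: return arma::clamp(Z, 0.0, arma::datum::inf);
    case 2: return 1.0 / (1.0 + arma::exp(-Z));
    default: return Z;
  }
}

// forward in evaluation mode; mode 1 = self-batch statistics,
// mode 2 = running statistics
arma::mat forward_eval(const std::vector<Layer>& net, const arma::mat& X,
                       int mode) {
  arma::mat A = X;
  for (size_t l = 0; l < net.size(); ++l) {
    const Layer& ly = net[l];
    arma::mat Z = ly.W * A;
    Z.each_col() += ly.b;
    if (ly.bn) {
      arma::vec mu, var;
      if (mode == 2 && ly.run_init) {
        mu = ly.run_mean; var = ly.run_var;
      } else {
        mu = arma::mean(Z, 1);
        var = arma::var(Z, 1, 1);  // 1/m normalization
      }
      Z.each_col() -= mu;
      Z.each_col() /= arma::sqrt(var + BN_EPS);
      Z.each_col() %= ly.gamma;
      Z.each_col() += ly.beta;
    }
    A = activate(Z, ly.act);
  }
  return A;  // logits (2 x n)
}

// mean softmax cross-entropy of logits vs labels
double softmax_ce(const arma::mat& logits, const arma::uvec& y) {
  double loss = 0.0;
  for (arma::uword j = 0; j < logits.n_cols; ++j) {
    double m = std::max(logits(0, j), logits(1, j));
    double lse = m + std::log(std::exp(logits(0, j) - m) +
                              std::exp(logits(1, j) - m));
    // unit 0 carries the concussion (label 1) probability
    double target = (y(j) == 1) ? logits(0, j) : logits(1, j);
    loss += lse - target;
  }
  return loss / logits.n_cols;
}

void adam_update(arma::mat& theta, arma::mat& m, arma::mat& v,
                 const arma::mat& g, double lr, double b1, double b2,
                 double eps, int t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  arma::mat mh = m / (1.0 - std::pow(b1, t));
  arma::mat vh = v / (1.0 - std::pow(b2, t));
  theta -= lr * mh / (arma::sqrt(vh) + eps);
}

void adam_update_vec(arma::vec& theta, arma::vec& m, arma::vec& v,
                     const arma::vec& g, double lr, double b1, double b2,
                     double eps, int t) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * arma::square(g);
  arma::vec mh = m / (1.0 - std::pow(b1, t));
  arma::vec vh = v / (1.0 - std::pow(b2, t));
  theta -= lr * mh / (arma::sqrt(vh) + eps);
}

}  // namespace

// [[Rcpp::export]]
List cpp_train_net(const arma::mat& X,            // d x n, all cases
                   const arma::uvec& y,           // n, 0/1
                   const arma::uvec& train_idx,   // 0-based
                   const arma::uvec& val_idx,     // 0-based
                   const List& inits,             // per restart: list(W=, b=)
                   const IntegerVector& act_codes,
                   const LogicalVector& bn_flags,
                   double lr, double beta1, double beta2, double eps,
                   int batch_size, int max_epochs, int min_epochs,
                   int probe_epochs, int patience, double rng_seed) {
  const arma::mat Xtr = X.cols(train_idx);
  const arma::mat Xval = X.cols(val_idx);
  const arma::uvec ytr = y.elem(train_idx);
  const arma::uvec yval = y.elem(val_idx);
  const arma::uword n_tr = Xtr.n_cols;
  const int L = act_codes.size();

  XorShift rng((uint64_t)rng_seed);

  std::vector<Layer> best_net;
  double best_val = arma::datum::inf;
  int best_epoch = -1, epochs_run = 0, restarts_used = 0;
  bool converged = false;
  std::vector<double> train_curve, val_curve;

  const int n_restarts = inits.size();
  for (int attempt = 0; attempt < n_restarts && !converged; ++attempt) {
    // build network from this attempt's initialization
    List ini = inits[attempt];
    List Ws = ini["W"], bs = ini["b"];
    std::vector<Layer> net(L);
    for (int l = 0; l < L; ++l) {
      Layer& ly = net[l];
      ly.W = as<arma::mat>(Ws[l]);
      ly.b = as<arma::vec>(bs[l]);
      ly.mW.zeros(ly.W.n_rows, ly.W.n_cols);
      ly.vW.zeros(ly.W.n_rows, ly.W.n_cols);
      ly.mb.zeros(ly.b.n_elem);
      ly.vb.zeros(ly.b.n_elem);
      ly.act = act_codes[l];
      ly.bn = bn_flags[l];
      if (ly.bn) {
        ly.gamma.ones(ly.W.n_rows);
        ly.beta.zeros(ly.W.n_rows);
        ly.mg.zeros(ly.W.n_rows); ly.vg.zeros(ly.W.n_rows);
        ly.mbe.zeros(ly.W.n_rows); ly.vbe.zeros(ly.W.n_rows);
        ly.run_mean.zeros(ly.W.n_rows);
        ly.run_var.ones(ly.W.n_rows);
        ly.run_init = false;
      }
    }

    double init_val = softmax_ce(forward_eval(net, Xval, 1), yval);
    double attempt_best = arma::datum::inf;
    int attempt_best_epoch = -1;
    std::vector<Layer> attempt_best_net;
    std::vector<double> a_train_curve, a_val_curve;
    int t_adam = 0;
    bool failed = false, nan_seen = false;

    arma::uvec order(n_tr);
    for (arma::uword i = 0; i < n_tr; ++i) order(i) = i;

    for (int epoch = 1; epoch <= max_epochs; ++epoch) {
      // Fisher-Yates shuffle
      for (arma::uword i = n_tr - 1; i > 0; --i) {
        arma::uword j = rng.below(i + 1);
        std::swap(order(i), order(j));
      }
      double epoch_loss = 0.0;
      int n_batches = 0;
      for (arma::uword start = 0; start < n_tr;
           start += (arma::uword)batch_size) {
        arma::uword m = std::min((arma::uword)batch_size, n_tr - start);
        arma::uvec bidx(batch_size);
        for (arma::uword i = 0; i < m; ++i) bidx(i) = order(start + i);
        // top up a short final batch with randomly resampled cases
        for (arma::uword i = m; i < (arma::uword)batch_size; ++i)
          bidx(i) = order(rng.below(n_tr));

        arma::mat A = Xtr.cols(bidx);
        arma::uvec yb = ytr.elem(bidx);
        arma::uword mb = A.n_cols;

        // forward with caches
        std::vector<arma::mat> As(L + 1), Zs(L), Xhat(L);
        std::vector<arma::vec> mus(L), vars(L);
        As[0] = A;
        for (int l = 0; l < L; ++l) {
          Layer& ly = net[l];
          arma::mat Z = ly.W * As[l];
          Z.each_col() += ly.b;
          if (ly.bn) {
            arma::vec mu = arma::mean(Z, 1);
            arma::vec var = arma::var(Z, 1, 1);
            mus[l] = mu; vars[l] = var;
            arma::mat Xc = Z;
            Xc.each_col() -= mu;
            Xc.each_col() /= arma::sqrt(var + BN_EPS);
            Xhat[l] = Xc;
            arma::mat Zn = Xc;
            Zn.each_col() %= ly.gamma;
            Zn.each_col() += ly.beta;
            Zs[l] = Zn;
            if (!ly.run_init) {
              ly.run_mean = mu; ly.run_var = var; ly.run_init = true;
            } else {
              ly.run_mean = BN_MOMENTUM * ly.run_mean + (1 - BN_MOMENTUM) * mu;
              ly.run_var = BN_MOMENTUM * ly.run_var + (1 - BN_MOMENTUM) * var;
            }
          } else {
            Zs[l] = Z;
          }
          As[l + 1] = activate(Zs[l], ly.act);
        }

        // softmax + CE loss
        arma::mat logits = As[L];
        arma::mat P(2, mb);
        for (arma::uword j = 0; j < mb; ++j) {
          double mx = std::max(logits(0, j), logits(1, j));
          double e0 = std::exp(logits(0, j) - mx);
          double e1 = std::exp(logits(1, j) - mx);
          P(0, j) = e0 / (e0 + e1);
          P(1, j) = e1 / (e0 + e1);
        }
        epoch_loss += softmax_ce(logits, yb);
        ++n_batches;

        // backward
        arma::mat D = P;  // dLoss/dlogits
        for (arma::uword j = 0; j < mb; ++j)
          D((yb(j) == 1) ? 0 : 1, j) -= 1.0;
        D /= (double)mb;

        ++t_adam;
        for (int l = L - 1; l >= 0; --l) {
          Layer& ly = net[l];
          // through the activation
          if (ly.act == 1) {
            D %= arma::conv_to<arma::mat>::from(Zs[l] > 0);
          } else if (ly.act == 2) {
            D %= As[l + 1] % (1.0 - As[l + 1]);
          }
          if (ly.bn) {
            arma::vec dgamma = arma::sum(D % Xhat[l], 1);
            arma::vec dbeta = arma::sum(D, 1);
            arma::vec inv_sd = 1.0 / arma::sqrt(vars[l] + BN_EPS);
            arma::vec mean_D = arma::mean(D, 1);
            arma::vec mean_DX = arma::mean(D % Xhat[l], 1);
            arma::mat Dx = D;
            Dx.each_col() -= mean_D;
            arma::mat corr = Xhat[l];
            corr.each_col() %= mean_DX;
            Dx -= corr;
            Dx.each_col() %= ly.gamma % inv_sd;
            D = Dx;
            adam_update_vec(ly.gamma, ly.mg, ly.vg, dgamma,
                            lr, beta1, beta2, eps, t_adam);
            adam_update_vec(ly.beta, ly.mbe, ly.vbe, dbeta,
                            lr, beta1, beta2, eps, t_adam);
          }
          arma::mat dW = D * As[l].t();
          arma::vec db = arma::sum(D, 1);
          if (l > 0) D = net[l].W.t() * D;
          adam_update(ly.W, ly.mW, ly.vW, dW, lr, beta1, beta2, eps, t_adam);
          adam_update_vec(ly.b, ly.mb, ly.vb, db, lr, beta1, beta2, eps,
                          t_adam);
        }
      }
      epoch_loss /= n_batches;
      if (!std::isfinite(epoch_loss)) { nan_seen = true; break; }

      double val_err = softmax_ce(forward_eval(net, Xval, 1), yval);
      a_train_curve.push_back(epoch_loss);
      a_val_curve.push_back(val_err);
      if (val_err < attempt_best) {
        attempt_best = val_err;
        attempt_best_epoch = epoch;
        attempt_best_net = net;
      }

      // probe: a run whose validation error never dropped below its initial
      // value is treated as a failed initialization
      if (epoch == probe_epochs && attempt_best >= init_val) {
        failed = true;
        break;
      }
      epochs_run = epoch;
      if (epoch >= min_epochs && epoch - attempt_best_epoch >= patience)
        break;
    }

    if (nan_seen) { failed = true; }
    if (failed) {
      ++restarts_used;
      continue;
    }
    converged = true;
    best_net = attempt_best_net;
    best_val = attempt_best;
    best_epoch = attempt_best_epoch;
    train_curve = a_train_curve;
    val_curve = a_val_curve;
  }

  if (!converged) {
    return List::create(Named("converged") = false,
                        Named("restarts_used") = restarts_used);
  }

  List Wout(L), bout(L);
  List bn_out(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = wrap(best_net[l].W);
    bout[l] = wrap(best_net[l].b);
    if (best_net[l].bn) {
      bn_out[l] = List::create(Named("gamma") = wrap(best_net[l].gamma),
                               Named("beta") = wrap(best_net[l].beta),
                               Named("mean") = wrap(best_net[l].run_mean),
                               Named("var") = wrap(best_net[l].run_var));
    } else {
      bn_out[l] = R_NilValue;
    }
  }
  return List::create(Named("converged") = true,
                      Named("W") = Wout, Named("b") = bout,
                      Named("bn") = bn_out,
                      Named("train_curve") = wrap(train_curve),
                      Named("val_curve") = wrap(val_curve),
                      Named("epochs_run") = (int)train_curve.size(),
                      Named("best_epoch") = best_epoch,
                      Named("best_val_error") = best_val,
                      Named("restarts_used") = restarts_used);
}
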