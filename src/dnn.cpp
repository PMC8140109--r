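// Feed-forward fully-connected network trained by mini-batch stochastic
// gradient descent with Adam and an L2 weight penalty.  One network = one
// ensemble member; bagging happens on the R side.  Inputs are expected to
// arrive standardized.  All randomness (init, shuffles, holdout) uses R's
// RNG so training is reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int runif_int(int n) {
  int v = static_cast<int>(unif_rand() * n);
  return v < n ? v : n - 1;
}

static arma::mat rnorm_mat(int r, int c, double sd) {
  arma::mat M(r, c);
  for (arma::uword k = 0; k < M.n_elem; ++k) M(k) = norm_rand() * sd;
  return M;
}

struct Net {
  std::vector<arma::mat> W;
  std::vector<arma::rowvec> b;
};

static arma::vec net_forward(const Net& net, const arma::mat& X,
                             bool classify) {
  arma::mat A = X;
  const size_t L = net.W.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    A = A * net.W[l];
    A.each_row() += net.b[l];
    A.transform([](double v) { return v > 0.0 ? v : 0.0; });
  }
  arma::mat Z = A * net.W[L - 1];
  Z.each_row() += net.b[L - 1];
  arma::vec out = Z.col(0);
  if (classify) out = 1.0 / (1.0 + arma::exp(-out));
  return out;
}

static double net_loss(const Net& net, const arma::mat& X,
                       const arma::vec& y, bool classify) {
  arma::vec p = net_forward(net, X, classify);
  if (classify) {
    arma::vec pc = arma::clamp(p, 1e-10, 1.0 - 1e-10);
    return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
  }
  return arma::mean(arma::square(y - p));
}

// [[Rcpp::export]]
List cpp_dnn_fit(const arma::mat& X, const arma::vec& y, bool classify,
                 IntegerVector hidden, int epochs, int batch,
                 double learning_rate, double lr_decay, double lambda,
                 double val_frac, int patience) {
  const int N = X.n_rows, p = X.n_cols;
  const int L = hidden.size() + 1;

  // layer dimensions: p -> hidden... -> 1
  std::vector<int> dims(L + 1);
  dims[0] = p;
  for (int l = 0; l < hidden.size(); ++l) dims[l + 1] = hidden[l];
  dims[L] = 1;

  // member-internal holdout for early stopping
  std::vector<int> ord(N);
  for (int i = 0; i < N; ++i) ord[i] = i;
  for (int i = N - 1; i > 0; --i) std::swap(ord[i], ord[runif_int(i + 1)]);
  int n_val = (patience > 0 && N >= 20)
    ? std::max(1, static_cast<int>(std::lround(val_frac * N))) : 0;
  int n_tr = N - n_val;
  arma::uvec tr_idx(n_tr), va_idx(std::max(n_val, 1));
  for (int i = 0; i < n_tr; ++i) tr_idx[i] = ord[i];
  for (int i = 0; i < n_val; ++i) va_idx[i] = ord[n_tr + i];
  arma::mat Xtr = X.rows(tr_idx);
  arma::vec ytr = y.elem(tr_idx);
  arma::mat Xva; arma::vec yva;
  if (n_val > 0) {
    va_idx.resize(n_val);
    Xva = X.rows(va_idx);
    yva = y.elem(va_idx);
  }

  // He-normal initialization
  Net net;
  std::vector<arma::mat> mW(L), vW(L);
  std::vector<arma::rowvec> mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    net.W.push_back(rnorm_mat(dims[l], dims[l + 1],
                              std::sqrt(2.0 / dims[l])));
    net.b.push_back(arma::rowvec(dims[l + 1], arma::fill::zeros));
    mW[l] = arma::mat(dims[l], dims[l + 1], arma::fill::zeros);
    vW[l] = mW[l];
    mb[l] = arma::rowvec(dims[l + 1], arma::fill::zeros);
    vb[l] = mb[l];
  }

  const double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  long step = 0;
  Net best = net;
  double best_loss = n_val > 0 ? net_loss(net, Xva, yva, classify) : 0.0;
  int stall = 0;

  std::vector<int> bord(n_tr);
  for (int i = 0; i < n_tr; ++i) bord[i] = i;
  if (batch > n_tr) batch = n_tr;

  std::vector<arma::mat> act(L + 1), delta(L);
  double lr = learning_rate;
  for (int ep = 0; ep < epochs; ++ep) {
    if (ep > 0) lr *= lr_decay;
    for (int i = n_tr - 1; i > 0; --i) std::swap(bord[i], bord[runif_int(i + 1)]);
    for (int off = 0; off < n_tr; off += batch) {
      int bs = std::min(batch, n_tr - off);
      arma::uvec bidx(bs);
      for (int i = 0; i < bs; ++i) bidx[i] = bord[off + i];
      act[0] = Xtr.rows(bidx);
      arma::vec yb = ytr.elem(bidx);

      for (int l = 0; l < L; ++l) {
        act[l + 1] = act[l] * net.W[l];
        act[l + 1].each_row() += net.b[l];
        if (l < L - 1) {
          act[l + 1].transform([](double v) { return v > 0.0 ? v : 0.0; });
        }
      }
      arma::vec pred = act[L].col(0);
      if (classify) pred = 1.0 / (1.0 + arma::exp(-pred));
      // d(loss)/d(output pre-activation); identical form for squared loss
      // with identity output (x2) and log-loss with sigmoid output
      arma::vec dz = (pred - yb) / bs;
      if (!classify) dz *= 2.0;
      delta[L - 1] = arma::mat(dz);
      for (int l = L - 1; l >= 0; --l) {
        arma::mat gW = act[l].t() * delta[l] + lambda * net.W[l];
        arma::rowvec gb = arma::sum(delta[l], 0);
        if (l > 0) {
          delta[l - 1] = delta[l] * net.W[l].t();
          delta[l - 1] %= arma::conv_to<arma::mat>::from(act[l] > 0.0);
        }
        ++step;
        double corr1 = 1.0 - std::pow(beta1, static_cast<double>(step));
        double corr2 = 1.0 - std::pow(beta2, static_cast<double>(step));
        mW[l] = beta1 * mW[l] + (1.0 - beta1) * gW;
        vW[l] = beta2 * vW[l] + (1.0 - beta2) * arma::square(gW);
        net.W[l] -= lr * (mW[l] / corr1) /
          (arma::sqrt(vW[l] / corr2) + adam_eps);
        mb[l] = beta1 * mb[l] + (1.0 - beta1) * gb;
        vb[l] = beta2 * vb[l] + (1.0 - beta2) * arma::square(gb);
        net.b[l] -= lr * (mb[l] / corr1) /
          (arma::sqrt(vb[l] / corr2) + adam_eps);
      }
    }
    if (n_val > 0) {
      double vl = net_loss(net, Xva, yva, classify);
      if (!std::isfinite(vl)) break; // diverged; keep best so far
      if (vl < best_loss - 1e-8) {
        best_loss = vl;
        best = net;
        stall = 0;
      } else if (++stall >= patience) {
        break;
      }
    }
  }
  if (n_val == 0) best = net;

  List W(L), b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = wrap(best.W[l]);
    b[l] = wrap(arma::vec(best.b[l].t()));
  }
  double final_train = net_loss(best, Xtr, ytr, classify);
  return List::create(_["W"] = W, _["b"] = b,
                      _["val_loss"] = n_val > 0 ? best_loss : NA_REAL,
                      _["train_loss"] = final_train);
}

// [[Rcpp::export]]
arma::vec cpp_dnn_predict(List weights, const arma::mat& X, bool classify) {
  List Wl = weights["W"], bl = weights["b"];
  Net net;
  for (int l = 0; l < Wl.size(); ++l) {
    net.W.push_back(as<arma::mat>(Wl[l]));
    net.b.push_back(as<arma::vec>(bl[l]).t());
  }
  return net_forward(net, X, classify);
}
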