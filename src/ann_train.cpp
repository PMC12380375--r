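// Minibatch Adam training loop for a small dense tanh network.
// The network layout, initial weights and data splits are prepared in R;
// this routine only iterates; arithmetic is single precision, the norm for
// dense-network training. Data are passed with samples as COLUMNS
// (features x n) so minibatch gathers are contiguous. Batch shuffling uses
// a seeded mt19937, reproducible independently of R's RNG state.
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// forward pass on samples-as-columns data; W[l] is (in x out)
template <typename MT, typename VT>
double val_mse(const std::vector<MT>& W, const std::vector<VT>& b,
               const MT& X, const MT& Y) {
  MT a = X;
  const size_t L = W.size();
  for (size_t l = 0; l < L; ++l) {
    a = W[l].t() * a;
    a.each_col() += b[l];
    if (l + 1 < L) a = tanh(a);
  }
  return accu(square(a - Y)) / (a.n_rows * a.n_cols);
}

template <typename MT, typename VT, typename ET>
Rcpp::List train_loop(const arma::mat& X, const arma::mat& Y,
                      const arma::mat& Xval, const arma::mat& Yval,
                      Rcpp::List W0, Rcpp::List b0,
                      int epochs, int batch, double lr,
                      int decay_epoch, double decay_factor,
                      int val_every, int shuffle_seed) {
  const size_t L = W0.size();
  const MT Xf = conv_to<MT>::from(X);
  const MT Yf = conv_to<MT>::from(Y);
  const MT Xvf = conv_to<MT>::from(Xval);
  const MT Yvf = conv_to<MT>::from(Yval);
  std::vector<MT> W(L), bestW, mW(L), vW(L), dW(L);
  std::vector<VT> b(L), bestb, mb(L), vb(L), db(L);
  for (size_t l = 0; l < L; ++l) {
    W[l] = conv_to<MT>::from(Rcpp::as<mat>(W0[l]));
    b[l] = conv_to<VT>::from(Rcpp::as<vec>(b0[l]));
    mW[l] = zeros<MT>(size(W[l]));
    vW[l] = zeros<MT>(size(W[l]));
    mb[l] = zeros<VT>(b[l].n_elem);
    vb[l] = zeros<VT>(b[l].n_elem);
  }
  const ET beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  const uword n = Xf.n_cols;
  std::mt19937 rng(static_cast<unsigned>(shuffle_seed));
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  double best_val = datum::inf;
  long iter = 0;
  std::vector<double> loss_hist;
  loss_hist.reserve(epochs);
  std::vector<MT> A(L + 1);

  for (int ep = 1; ep <= epochs; ++ep) {
    ET lr_ep = static_cast<ET>(lr);
    if (decay_epoch > 0 && ep >= decay_epoch) lr_ep = static_cast<ET>(lr * decay_factor);
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    uword nb = 0;
    for (uword s = 0; s < n; s += batch) {
      const uword e = std::min<uword>(s + batch, n) - 1;
      uvec idx(e - s + 1);
      for (uword i = s; i <= e; ++i) idx[i - s] = order[i];
      A[0] = Xf.cols(idx);                     // features x batch
      const MT Yb = Yf.cols(idx);
      for (size_t l = 0; l < L; ++l) {
        A[l + 1] = W[l].t() * A[l];
        A[l + 1].each_col() += b[l];
        if (l + 1 < L) A[l + 1] = tanh(A[l + 1]);
      }
      MT delta = A[L] - Yb;                    // outputs x batch
      ep_loss += accu(square(delta)) / (delta.n_rows * delta.n_cols);
      ++nb;
      delta *= static_cast<ET>(2.0) / (delta.n_rows * delta.n_cols);
      for (size_t li = L; li-- > 0;) {
        dW[li] = A[li] * delta.t();
        db[li] = sum(delta, 1);
        if (li > 0) {
          delta = W[li] * delta;
          delta %= (static_cast<ET>(1.0) - square(A[li]));  // tanh deriv
        }
      }
      ++iter;
      const ET bc1 = static_cast<ET>(1.0) - std::pow(beta1, static_cast<ET>(iter));
      const ET bc2 = static_cast<ET>(1.0) - std::pow(beta2, static_cast<ET>(iter));
      for (size_t l = 0; l < L; ++l) {
        mW[l] = beta1 * mW[l] + (1 - beta1) * dW[l];
        vW[l] = beta2 * vW[l] + (1 - beta2) * square(dW[l]);
        W[l] -= lr_ep * (mW[l] / bc1) / (sqrt(vW[l] / bc2) + eps);
        mb[l] = beta1 * mb[l] + (1 - beta1) * db[l];
        vb[l] = beta2 * vb[l] + (1 - beta2) * square(db[l]);
        b[l] -= lr_ep * (mb[l] / bc1) / (sqrt(vb[l] / bc2) + eps);
      }
    }
    ep_loss /= nb;
    loss_hist.push_back(ep_loss);
    if (!std::isfinite(ep_loss))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep);
    if (ep % val_every == 0 || ep == epochs) {
      const double v = val_mse(W, b, Xvf, Yvf);
      if (v < best_val) {
        best_val = v;
        bestW = W;
        bestb = b;
      }
    }
  }
  if (bestW.empty()) { bestW = W; bestb = b; }
  Rcpp::List Wout(L), bout(L);
  for (size_t l = 0; l < L; ++l) {
    Wout[l] = conv_to<mat>::from(bestW[l]);
    vec bd = conv_to<vec>::from(bestb[l]);
    bout[l] = Rcpp::NumericVector(bd.begin(), bd.end());
  }
  return Rcpp::List::create(Rcpp::Named("W") = Wout,
                            Rcpp::Named("b") = bout,
                            Rcpp::Named("best_val") = best_val,
                            Rcpp::Named("loss") = loss_hist);
}

}  // namespace

// [[Rcpp::export(name = ".ann_train_cpp")]]
Rcpp::List ann_train_cpp(const arma::mat& X, const arma::mat& Y,
                         const arma::mat& Xval, const arma::mat& Yval,
                         Rcpp::List W0, Rcpp::List b0,
                         int epochs, int batch, double lr,
                         int decay_epoch, double decay_factor,
                         int val_every, int shuffle_seed,
                         bool double_precision) {
#ifdef __GLIBC__
  // batch-sized temporaries churn through malloc; without this they hit the
  // mmap path and page-fault costs dominate the arithmetic
  mallopt(M_MMAP_THRESHOLD, 1 << 26);
#endif
  if (double_precision)
    return train_loop<mat, vec, double>(X, Y, Xval, Yval, W0, b0, epochs,
                                        batch, lr, decay_epoch, decay_factor,
                                        val_every, shuffle_seed);
  return train_loop<fmat, fvec, float>(X, Y, Xval, Yval, W0, b0, epochs,
                                       batch, lr, decay_epoch, decay_factor,
                                       val_every, shuffle_seed);
}
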