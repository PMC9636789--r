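// Batched 1-D convolution / batch-norm kernels.
//
// A batch of B length-L sequences with C channels is a (B*L) x C matrix with
// sample-major rows. A dilated convolution of width W is a sum of W shifted
// matrix products; the shifts never cross sample boundaries. Heavy products
// go through Armadillo (BLAS); the shifts are submatrix-view adds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Y += shift(P, o) within each sample block: Y[l] += P[l + o].
static void shift_add(arma::mat& Y, const arma::mat& P, int o, int B, int L) {
  for (int b = 0; b < B; ++b) {
    int base = b * L;
    if (o >= 0) {
      if (o < L)
        Y.rows(base, base + L - 1 - o) += P.rows(base + o, base + L - 1);
    } else {
      int k = -o;
      if (k < L)
        Y.rows(base + k, base + L - 1) += P.rows(base, base + L - 1 - k);
    }
  }
}

// [[Rcpp::export]]
arma::mat cpp_conv_fwd(const arma::mat& X, const List& Ws,
                       const arma::rowvec& bias, const IntegerVector& offsets,
                       int B, int L) {
  arma::mat Y(X.n_rows, as<arma::mat>(Ws[0]).n_cols, arma::fill::zeros);
  for (int t = 0; t < Ws.size(); ++t) {
    arma::mat W = as<arma::mat>(Ws[t]);
    arma::mat P = X * W;
    shift_add(Y, P, offsets[t], B, L);
  }
  Y.each_row() += bias;
  return Y;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& dY, const arma::mat& X, const List& Ws,
                  const IntegerVector& offsets, int B, int L) {
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  List dWs(Ws.size());
  for (int t = 0; t < Ws.size(); ++t) {
    arma::mat W = as<arma::mat>(Ws[t]);
    // S = shift(dY, -o): S[m] = dY[m - o]
    arma::mat S(dY.n_rows, dY.n_cols, arma::fill::zeros);
    shift_add(S, dY, -offsets[t], B, L);
    dWs[t] = X.t() * S;
    dX += S * W.t();
  }
  arma::rowvec db = arma::sum(dY, 0);
  return List::create(_["dW"] = dWs, _["db"] = db, _["dX"] = dX);
}

// Fused batch-norm + ReLU (training): one stats pass and one write pass per
// channel. Returns the ReLU output, the normalized pre-activation xhat (for
// the backward pass) and the batch statistics.
// [[Rcpp::export]]
List cpp_bnrelu_fwd_train(const arma::mat& X, const arma::vec& gamma,
                          const arma::vec& beta, double eps) {
  int n = X.n_rows, C = X.n_cols;
  arma::mat Y(n, C), xhat(n, C);
  arma::vec mu(C), v(C), inv(C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double s1 = 0.0, s2 = 0.0;
    for (int i = 0; i < n; ++i) { s1 += x[i]; s2 += x[i] * x[i]; }
    double m = s1 / n;
    double var = s2 / n - m * m;
    if (var < 0) var = 0;
    double iv = 1.0 / std::sqrt(var + eps);
    mu[c] = m; v[c] = var; inv[c] = iv;
    double g = gamma[c], b = beta[c];
    double* xh = xhat.colptr(c);
    double* y = Y.colptr(c);
    for (int i = 0; i < n; ++i) {
      double z = (x[i] - m) * iv;
      xh[i] = z;
      double a = g * z + b;
      y[i] = a > 0 ? a : 0.0;
    }
  }
  return List::create(_["Y"] = Y, _["xhat"] = xhat, _["inv"] = inv,
                      _["mu"] = mu, _["var"] = v);
}

// Fused batch-norm + ReLU (evaluation, running statistics).
// [[Rcpp::export]]
arma::mat cpp_bnrelu_fwd_eval(const arma::mat& X, const arma::vec& gamma,
                              const arma::vec& beta, const arma::vec& run_mean,
                              const arma::vec& run_var, double eps) {
  int n = X.n_rows, C = X.n_cols;
  arma::mat Y(n, C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* y = Y.colptr(c);
    double iv = 1.0 / std::sqrt(run_var[c] + eps);
    double g = gamma[c], b = beta[c], m = run_mean[c];
    for (int i = 0; i < n; ++i) {
      double a = g * (x[i] - m) * iv + b;
      y[i] = a > 0 ? a : 0.0;
    }
  }
  return Y;
}

// Backward of the fused BN+ReLU. dY is the gradient at the ReLU output;
// the ReLU mask is recomputed from xhat.
// [[Rcpp::export]]
List cpp_bnrelu_bwd(const arma::mat& dY, const arma::vec& gamma,
                    const arma::vec& beta, const arma::mat& xhat,
                    const arma::vec& inv) {
  int n = dY.n_rows, C = dY.n_cols;
  arma::mat dX(n, C);
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const double* xh = xhat.colptr(c);
    double* dx = dX.colptr(c);
    double g = gamma[c], b = beta[c], iv = inv[c];
    double s1 = 0.0, s2 = 0.0, sg = 0.0;
    for (int i = 0; i < n; ++i) {
      bool on = (g * xh[i] + b) > 0;
      double da = on ? dy[i] : 0.0;
      dx[i] = da;           // stash da; rewritten below
      s1 += da;
      s2 += da * xh[i];
    }
    sg = s2;
    double m1 = s1 / n, m2 = s2 / n;
    double giv = g * iv;
    for (int i = 0; i < n; ++i) {
      dx[i] = giv * (dx[i] - m1 - xh[i] * m2);
    }
    dgamma[c] = sg;
    dbeta[c] = s1;
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta,
                      _["dX"] = dX);
}

// [[Rcpp::export]]
arma::mat cpp_relu(const arma::mat& X) {
  return arma::clamp(X, 0.0, arma::datum::inf);
}

// [[Rcpp::export]]
arma::mat cpp_relu_bwd(const arma::mat& dY, const arma::mat& Xpre) {
  return dY % arma::conv_to<arma::mat>::from(Xpre > 0);
}
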