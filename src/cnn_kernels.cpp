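// Compiled kernels for the 1-D CNN hot path: im2col convolution
// forward/backward, batch normalization, and width-2 max pooling.
// Inputs and outputs are wrapped with Armadillo views over R memory
// (no copies); everything stochastic (weight init, shuffling, dropout
// masks) stays on the R side so runs are reproducible from R's RNG alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SELU_L = 1.0507009873554805;
static const double SELU_A = 1.6732632423543772;

static inline arma::mat view(NumericMatrix m) {
  return arma::mat(m.begin(), m.nrow(), m.ncol(), false, true);
}

// activation codes: 0 = relu, 1 = sigmoid, 2 = selu
static void act_fwd_inplace(arma::mat& a, const arma::mat& z, const int act) {
  if (act == 0) {
    a = arma::clamp(z, 0.0, arma::datum::inf);
  } else if (act == 1) {
    a = 1.0 / (1.0 + arma::exp(-z));
  } else {
    a = SELU_L * z;
    arma::uvec neg = arma::find(z < 0);
    a.elem(neg) = SELU_L * SELU_A * (arma::exp(z.elem(neg)) - 1.0);
  }
}

static arma::mat act_bwd(const arma::mat& da, const arma::mat& z,
                         const arma::mat& a, const int act) {
  if (act == 0) return da % arma::conv_to<arma::mat>::from(z > 0);
  if (act == 1) return da % a % (1.0 - a);
  arma::mat g(z.n_rows, z.n_cols);
  g.fill(SELU_L);
  arma::uvec neg = arma::find(z < 0);
  g.elem(neg) = a.elem(neg) + SELU_L * SELU_A;
  return da % g;
}

// xm: nb x (len*ch); idx: out_len x R, 1-based columns of xm;
// w: R x F; b: F. Returns the patch matrix p (nb*out_len x R) plus the
// pre-activation z and activation a (both nb*out_len x F).
// [[Rcpp::export]]
List cpp_conv_forward(NumericMatrix xm_, IntegerMatrix idx,
                      NumericMatrix w_, NumericVector b, const int act) {
  const arma::mat xm = view(xm_);
  const arma::mat w = view(w_);
  const int nb = xm.n_rows, out_len = idx.nrow(), r_dim = idx.ncol();
  const int f_dim = w.n_cols;

  NumericMatrix p_(nb * out_len, r_dim);
  arma::mat p = view(p_);
  for (int r = 0; r < r_dim; ++r) {
    for (int j = 0; j < out_len; ++j) {
      p.submat(j * nb, r, (j + 1) * nb - 1, r) = xm.col(idx(j, r) - 1);
    }
  }
  NumericMatrix z_(nb * out_len, f_dim);
  arma::mat z = view(z_);
  z = p * w;
  for (int f = 0; f < f_dim; ++f) z.col(f) += b[f];
  NumericMatrix a_(nb * out_len, f_dim);
  arma::mat a = view(a_);
  act_fwd_inplace(a, z, act);
  return List::create(_["p"] = p_, _["z"] = z_, _["a"] = a_);
}

// [[Rcpp::export]]
List cpp_conv_backward(NumericMatrix dym_, NumericMatrix p_, NumericMatrix z_,
                       NumericMatrix a_, NumericMatrix w_, IntegerMatrix idx,
                       const int act, const int nb, const int in_cols) {
  const arma::mat dym = view(dym_), p = view(p_), z = view(z_),
                  a = view(a_), w = view(w_);
  arma::mat dz = act_bwd(dym, z, a, act);

  NumericMatrix dw_(w.n_rows, w.n_cols);
  arma::mat dw = view(dw_);
  dw = p.t() * dz;
  NumericVector db_(w.n_cols);
  arma::rowvec db = arma::sum(dz, 0);
  std::copy(db.begin(), db.end(), db_.begin());

  arma::mat dp = dz * w.t();
  const int out_len = idx.nrow(), r_dim = idx.ncol();
  NumericMatrix dxm_(nb, in_cols);
  arma::mat dxm = view(dxm_);
  for (int r = 0; r < r_dim; ++r) {
    for (int j = 0; j < out_len; ++j) {
      dxm.col(idx(j, r) - 1) += dp.submat(j * nb, r, (j + 1) * nb - 1, r);
    }
  }
  return List::create(_["dx"] = dxm_, _["dw"] = dw_, _["db"] = db_);
}

// xm: m x F (batch*positions by channels). Training mode computes batch
// statistics (biased variance) and returns updated running moments.
// [[Rcpp::export]]
List cpp_bn_forward(NumericMatrix xm_, NumericVector gamma, NumericVector beta,
                    NumericVector run_mean, NumericVector run_var,
                    const bool training, const double momentum,
                    const double eps) {
  const arma::mat xm = view(xm_);
  const int m = xm.n_rows, f_dim = xm.n_cols;
  NumericVector new_mean(f_dim), new_var(f_dim), invstd_(f_dim);
  NumericMatrix xhat_(m, f_dim), y_(m, f_dim);
  arma::mat xhat = view(xhat_), y = view(y_);

  for (int f = 0; f < f_dim; ++f) {
    double mu, va;
    if (training) {
      mu = arma::mean(xm.col(f));
      va = 0.0;
      for (int i = 0; i < m; ++i) {
        const double d = xm(i, f) - mu;
        va += d * d;
      }
      va /= m;
      new_mean[f] = momentum * run_mean[f] + (1.0 - momentum) * mu;
      new_var[f] = momentum * run_var[f] + (1.0 - momentum) * va;
    } else {
      mu = run_mean[f];
      va = run_var[f];
      new_mean[f] = mu;
      new_var[f] = va;
    }
    const double is = 1.0 / std::sqrt(va + eps);
    invstd_[f] = is;
    xhat.col(f) = (xm.col(f) - mu) * is;
    y.col(f) = xhat.col(f) * gamma[f] + beta[f];
  }
  return List::create(_["y"] = y_, _["xhat"] = xhat_, _["invstd"] = invstd_,
                      _["run_mean"] = new_mean, _["run_var"] = new_var);
}

// [[Rcpp::export]]
List cpp_bn_backward(NumericMatrix dym_, NumericMatrix xhat_,
                     NumericVector invstd, NumericVector gamma) {
  const arma::mat dym = view(dym_), xhat = view(xhat_);
  const int m = dym.n_rows, f_dim = dym.n_cols;
  NumericVector dgamma(f_dim), dbeta(f_dim);
  NumericMatrix dx_(m, f_dim);
  arma::mat dx = view(dx_);
  for (int f = 0; f < f_dim; ++f) {
    const double db = arma::accu(dym.col(f));
    const double dg = arma::dot(dym.col(f), xhat.col(f));
    dbeta[f] = db;
    dgamma[f] = dg;
    dx.col(f) = (dym.col(f) - db / m - xhat.col(f) * (dg / m)) *
      (gamma[f] * invstd[f]);
  }
  return List::create(_["dx"] = dx_, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// x: flat (nb, len, F) array; width-2 stride-2 pooling along the length
// axis (odd leftover position dropped). Ties go to the earlier position.
// [[Rcpp::export]]
List cpp_pool_forward(NumericVector x, const int nb, const int len,
                      const int f_dim, const int out_len) {
  NumericVector y(nb * out_len * f_dim);
  LogicalVector first(nb * out_len * f_dim);
  const double* px = x.begin();
  double* py = y.begin();
  int* pf = first.begin();
  for (int f = 0; f < f_dim; ++f) {
    const double* xf = px + (R_xlen_t) f * nb * len;
    double* yf = py + (R_xlen_t) f * nb * out_len;
    int* ff = pf + (R_xlen_t) f * nb * out_len;
    for (int j = 0; j < out_len; ++j) {
      const double* c1 = xf + (R_xlen_t) (2 * j) * nb;
      const double* c2 = xf + (R_xlen_t) (2 * j + 1) * nb;
      double* yj = yf + (R_xlen_t) j * nb;
      int* fj = ff + (R_xlen_t) j * nb;
      for (int b = 0; b < nb; ++b) {
        const bool take1 = c1[b] >= c2[b];
        yj[b] = take1 ? c1[b] : c2[b];
        fj[b] = take1;
      }
    }
  }
  return List::create(_["y"] = y, _["first"] = first);
}

// [[Rcpp::export]]
NumericVector cpp_pool_backward(NumericVector dout, LogicalVector first,
                                const int nb, const int in_len,
                                const int f_dim, const int out_len) {
  NumericVector dx(nb * in_len * f_dim);  // zero-initialized
  const double* pd = dout.begin();
  const int* pf = first.begin();
  double* px = dx.begin();
  for (int f = 0; f < f_dim; ++f) {
    const double* df = pd + (R_xlen_t) f * nb * out_len;
    const int* ff = pf + (R_xlen_t) f * nb * out_len;
    double* xf = px + (R_xlen_t) f * nb * in_len;
    for (int j = 0; j < out_len; ++j) {
      const double* dj = df + (R_xlen_t) j * nb;
      const int* fj = ff + (R_xlen_t) j * nb;
      double* x1 = xf + (R_xlen_t) (2 * j) * nb;
      double* x2 = xf + (R_xlen_t) (2 * j + 1) * nb;
      for (int b = 0; b < nb; ++b) {
        if (fj[b]) x1[b] = dj[b]; else x2[b] = dj[b];
      }
    }
  }
  return dx;
}
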