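// Convolution / transposed-convolution kernels for the DCGAN networks.
//
// Array layout conventions (R column-major):
//   activations x : dim (H, W, C, N)
//   conv weights  : dim (k, k, Cin, Cout)   -- strided convolution
//   tconv weights : dim (k, k, Cout, Cin)   -- fractional-stride convolution
//
// im2col row index for a (c, kh, kw) tap is ((c * k) + kh) * k + kw, matching
// the weight-matrix flattening below, so each layer reduces to one GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// x_n: pointer to one sample (H, W, C) column-major; fills cols (C*k*k, Ho*Wo)
static void im2col_one(const double* x, int H, int W, int C,
                       int k, int stride, int pad, arma::mat& cols) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int col = ow * Ho + oh;
      for (int c = 0; c < C; ++c) {
        for (int kh = 0; kh < k; ++kh) {
          const int ih = oh * stride - pad + kh;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            const int row = (c * k + kh) * k + kw;
            cols(row, col) =
              (ih >= 0 && ih < H && iw >= 0 && iw < W)
                ? x[ih + H * (iw + W * c)] : 0.0;
          }
        }
      }
    }
  }
}

// adjoint of im2col_one: accumulates cols back into x (H, W, C)
static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int k, int stride, int pad, double* x) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int ow = 0; ow < Wo; ++ow) {
    for (int oh = 0; oh < Ho; ++oh) {
      const int col = ow * Ho + oh;
      for (int c = 0; c < C; ++c) {
        for (int kh = 0; kh < k; ++kh) {
          const int ih = oh * stride - pad + kh;
          if (ih < 0 || ih >= H) continue;
          for (int kw = 0; kw < k; ++kw) {
            const int iw = ow * stride - pad + kw;
            if (iw < 0 || iw >= W) continue;
            x[ih + H * (iw + W * c)] += cols((c * k + kh) * k + kw, col);
          }
        }
      }
    }
  }
}

// weights (k, k, Cin, Cout) -> Wm (Cin*k*k, Cout) with im2col row order
static arma::mat flatten_conv_w(const NumericVector& Wv,
                                int k, int Cin, int Cout) {
  arma::mat Wm(Cin * k * k, Cout);
  const double* w = Wv.begin();
  for (int f = 0; f < Cout; ++f)
    for (int c = 0; c < Cin; ++c)
      for (int kh = 0; kh < k; ++kh)
        for (int kw = 0; kw < k; ++kw)
          Wm((c * k + kh) * k + kw, f) = w[kh + k * (kw + k * (c + Cin * f))];
  return Wm;
}

static void unflatten_conv_w(const arma::mat& Wm, int k, int Cin, int Cout,
                             NumericVector& Wv) {
  double* w = Wv.begin();
  for (int f = 0; f < Cout; ++f)
    for (int c = 0; c < Cin; ++c)
      for (int kh = 0; kh < k; ++kh)
        for (int kw = 0; kw < k; ++kw)
          w[kh + k * (kw + k * (c + Cin * f))] = Wm((c * k + kh) * k + kw, f);
}

static IntegerVector dims_of(const NumericVector& x) {
  return as<IntegerVector>(x.attr("dim"));
}

// [[Rcpp::export(name = ".cpp_conv2d_fwd")]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector W,
                             NumericVector b, int stride, int pad) {
  IntegerVector dx = dims_of(x), dw = dims_of(W);
  const int H = dx[0], Wd = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  const int Ho = out_size(H, k, stride, pad), Wo = out_size(Wd, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("output size would be empty");
  arma::mat Wm = flatten_conv_w(W, k, Cin, Cout);
  arma::vec bv(b.begin(), Cout);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(C * k * k, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + (R_xlen_t)n * H * Wd * C, H, Wd, C, k, stride, pad,
               cols);
    arma::mat out = Wm.t() * cols;           // (Cout, Ho*Wo)
    out.each_col() += bv;
    // out(f, col) -> y[oh, ow, f, n]; col = ow*Ho + oh
    double* yp = y.begin() + (R_xlen_t)n * Ho * Wo * Cout;
    for (int f = 0; f < Cout; ++f)
      for (int col = 0; col < Ho * Wo; ++col) {
        const int oh = col % Ho, ow = col / Ho;
        yp[oh + Ho * (ow + Wo * f)] = out(f, col);
      }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_conv2d_bwd")]]
List cpp_conv2d_bwd(NumericVector x, NumericVector W, NumericVector dy,
                    int stride, int pad) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(W), dyd = dims_of(dy);
  const int H = dx_[0], Wd = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cin = dw_[2], Cout = dw_[3];
  const int Ho = dyd[0], Wo = dyd[1];
  arma::mat Wm = flatten_conv_w(W, k, Cin, Cout);
  NumericVector dxv(x.size());
  dxv.attr("dim") = dx_;
  arma::mat dWm(Cin * k * k, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(C * k * k, Ho * Wo), dy_mat(Cout, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (R_xlen_t)n * Ho * Wo * Cout;
    for (int f = 0; f < Cout; ++f)
      for (int col = 0; col < Ho * Wo; ++col) {
        const int oh = col % Ho, ow = col / Ho;
        dy_mat(f, col) = dyp[oh + Ho * (ow + Wo * f)];
      }
    im2col_one(x.begin() + (R_xlen_t)n * H * Wd * C, H, Wd, C, k, stride, pad,
               cols);
    dWm += cols * dy_mat.t();
    db += arma::sum(dy_mat, 1);
    arma::mat dcols = Wm * dy_mat;           // (C*k*k, Ho*Wo)
    col2im_one(dcols, H, Wd, C, k, stride, pad,
               dxv.begin() + (R_xlen_t)n * H * Wd * C);
  }
  NumericVector dW(W.size());
  dW.attr("dim") = dw_;
  unflatten_conv_w(dWm, k, Cin, Cout, dW);
  return List::create(_["dx"] = dxv, _["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// weights (k, k, Cout, Cin) -> Wm (Cout*k*k, Cin)
static arma::mat flatten_tconv_w(const NumericVector& Wv,
                                 int k, int Cout, int Cin) {
  arma::mat Wm(Cout * k * k, Cin);
  const double* w = Wv.begin();
  for (int c = 0; c < Cin; ++c)
    for (int f = 0; f < Cout; ++f)
      for (int kh = 0; kh < k; ++kh)
        for (int kw = 0; kw < k; ++kw)
          Wm((f * k + kh) * k + kw, c) = w[kh + k * (kw + k * (f + Cout * c))];
  return Wm;
}

static void unflatten_tconv_w(const arma::mat& Wm, int k, int Cout, int Cin,
                              NumericVector& Wv) {
  double* w = Wv.begin();
  for (int c = 0; c < Cin; ++c)
    for (int f = 0; f < Cout; ++f)
      for (int kh = 0; kh < k; ++kh)
        for (int kw = 0; kw < k; ++kw)
          w[kh + k * (kw + k * (f + Cout * c))] = Wm((f * k + kh) * k + kw, c);
}

// [[Rcpp::export(name = ".cpp_tconv2d_fwd")]]
NumericVector cpp_tconv2d_fwd(NumericVector x, NumericVector W,
                              NumericVector b, int stride, int pad) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(W);
  const int H = dx_[0], Wd = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cout = dw_[2], Cin = dw_[3];
  if (Cin != C) stop("channel mismatch between input and weights");
  const int Ho = (H - 1) * stride - 2 * pad + k;
  const int Wo = (Wd - 1) * stride - 2 * pad + k;
  if (Ho < 1 || Wo < 1) stop("output size would be empty");
  arma::mat Wm = flatten_tconv_w(W, k, Cout, Cin);
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat x_mat(C, H * Wd);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (R_xlen_t)n * H * Wd * C;
    for (int c = 0; c < C; ++c)
      for (int col = 0; col < H * Wd; ++col) {
        const int ih = col % H, iw = col / H;
        x_mat(c, col) = xp[ih + H * (iw + Wd * c)];
      }
    arma::mat cols = Wm * x_mat;             // (Cout*k*k, H*Wd)
    double* yp = y.begin() + (R_xlen_t)n * Ho * Wo * Cout;
    col2im_one(cols, Ho, Wo, Cout, k, stride, pad, yp);
    for (int f = 0; f < Cout; ++f) {
      const double bf = b[f];
      for (int j = 0; j < Ho * Wo; ++j) yp[j + Ho * Wo * f] += bf;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".cpp_tconv2d_bwd")]]
List cpp_tconv2d_bwd(NumericVector x, NumericVector W, NumericVector dy,
                     int stride, int pad) {
  IntegerVector dx_ = dims_of(x), dw_ = dims_of(W), dyd = dims_of(dy);
  const int H = dx_[0], Wd = dx_[1], C = dx_[2], N = dx_[3];
  const int k = dw_[0], Cout = dw_[2], Cin = dw_[3];
  const int Ho = dyd[0], Wo = dyd[1];
  arma::mat Wm = flatten_tconv_w(W, k, Cout, Cin);
  NumericVector dxv(x.size());
  dxv.attr("dim") = dx_;
  arma::mat dWm(Cout * k * k, Cin, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat dcols(Cout * k * k, H * Wd), x_mat(C, H * Wd);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (R_xlen_t)n * Ho * Wo * Cout;
    im2col_one(dyp, Ho, Wo, Cout, k, stride, pad, dcols);
    const double* xp = x.begin() + (R_xlen_t)n * H * Wd * C;
    for (int c = 0; c < C; ++c)
      for (int col = 0; col < H * Wd; ++col) {
        const int ih = col % H, iw = col / H;
        x_mat(c, col) = xp[ih + H * (iw + Wd * c)];
      }
    arma::mat dx_mat = Wm.t() * dcols;       // (Cin, H*Wd)
    double* dxp = dxv.begin() + (R_xlen_t)n * H * Wd * C;
    for (int c = 0; c < C; ++c)
      for (int col = 0; col < H * Wd; ++col) {
        const int ih = col % H, iw = col / H;
        dxp[ih + H * (iw + Wd * c)] += dx_mat(c, col);
      }
    dWm += dcols * x_mat.t();
    for (int f = 0; f < Cout; ++f) {
      double s = 0.0;
      for (int j = 0; j < Ho * Wo; ++j) s += dyp[j + Ho * Wo * f];
      db[f] += s;
    }
  }
  NumericVector dW(W.size());
  dW.attr("dim") = dw_;
  unflatten_tconv_w(dWm, k, Cout, Cin, dW);
  return List::create(_["dx"] = dxv, _["dW"] = dW,
                      _["db"] = NumericVector(db.begin(), db.end()));
}
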