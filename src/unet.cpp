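// Fast path for the tiny encoder-decoder: one C++ call per image runs the
// whole forward (and, when a target is given, backward) pass.  The R-level
// layer functions in R/backbone.R implement the same computation and serve
// as the reference in tests; this file must match them exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::uword;

static void im2col(const mat& X, int H, int W, mat& out) {
  const int C = X.n_cols;
  out.zeros(H * W, 9 * C);
  int k = 0;
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int cc0 = dc < 0 ? 1 : 0, cc1 = dc > 0 ? W - 1 : W;
      for (int dr = -1; dr <= 1; ++dr) {
        const int r0 = dr < 0 ? 1 : 0, r1 = dr > 0 ? H - 1 : H;
        const double* src = X.colptr(c);
        double* dst = out.colptr(k);
        for (int cc = cc0; cc < cc1; ++cc) {
          const double* s = src + (cc + dc) * H + dr;
          double* d = dst + cc * H;
          for (int r = r0; r < r1; ++r) d[r] = s[r];
        }
        ++k;
      }
    }
  }
}

static void col2im_acc(const mat& dcol, int H, int W, mat& dX) {
  const int C = dX.n_cols;
  int k = 0;
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      const int cc0 = dc < 0 ? 1 : 0, cc1 = dc > 0 ? W - 1 : W;
      for (int dr = -1; dr <= 1; ++dr) {
        const int r0 = dr < 0 ? 1 : 0, r1 = dr > 0 ? H - 1 : H;
        const double* s0 = dcol.colptr(k);
        double* d0 = dX.colptr(c);
        for (int cc = cc0; cc < cc1; ++cc) {
          const double* s = s0 + cc * H;
          double* d = d0 + (cc + dc) * H + dr;
          for (int r = r0; r < r1; ++r) d[r] += s[r];
        }
        ++k;
      }
    }
  }
}

struct ConvCache { mat Xcol; mat A; };

static mat conv_relu(const mat& X, int H, int W, const mat& Wm,
                     const arma::rowvec& b, ConvCache& cc) {
  im2col(X, H, W, cc.Xcol);
  mat A = cc.Xcol * Wm;
  A.each_row() += b;
  A.for_each([](double& v) { if (v < 0) v = 0; });
  cc.A = A;
  return A;
}

// dA in, returns dX; accumulates dW/db into the provided grads.
static mat conv_relu_bwd(const mat& dA, const ConvCache& cc, const mat& Wm,
                         int H, int W, int Cin, mat& dW, arma::rowvec& db) {
  mat dZ = dA % (cc.A > 0);
  dW = cc.Xcol.t() * dZ;
  db = arma::sum(dZ, 0);
  mat dXcol = dZ * Wm.t();
  mat dX(H * W, Cin, arma::fill::zeros);
  col2im_acc(dXcol, H, W, dX);
  return dX;
}

static mat pool_fwd(const mat& X, int H, int W, arma::umat& argm) {
  const int C = X.n_cols, h2 = H / 2, w2 = W / 2;
  mat out(h2 * w2, C);
  argm.set_size(h2 * w2, C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* o = out.colptr(c);
    uword* a = argm.colptr(c);
    for (int cc = 0; cc < w2; ++cc) {
      for (int r = 0; r < h2; ++r) {
        const int base = 2 * r + 2 * cc * H;
        int idx = base; double m = x[base];
        // candidate order matches the R reference (down, right, diagonal)
        if (x[base + 1] > m) { m = x[base + 1]; idx = base + 1; }
        if (x[base + H] > m) { m = x[base + H]; idx = base + H; }
        if (x[base + H + 1] > m) { m = x[base + H + 1]; idx = base + H + 1; }
        o[r + cc * h2] = m; a[r + cc * h2] = idx;
      }
    }
  }
  return out;
}

static mat pool_bwd(const mat& dY, const arma::umat& argm, int H, int W) {
  const int C = dY.n_cols;
  mat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* dy = dY.colptr(c);
    const uword* a = argm.colptr(c);
    double* dx = dX.colptr(c);
    for (uword i = 0; i < dY.n_rows; ++i) dx[a[i]] += dy[i];
  }
  return dX;
}

static mat up_fwd(const mat& X, int H, int W) {
  const int C = X.n_cols, H2 = 2 * H, W2 = 2 * W;
  mat out(H2 * W2, C);
  for (int c = 0; c < C; ++c) {
    const double* x = X.colptr(c);
    double* o = out.colptr(c);
    for (int cc = 0; cc < W2; ++cc) {
      const double* xc = x + (cc / 2) * H;
      double* oc = o + cc * H2;
      for (int r = 0; r < H2; ++r) oc[r] = xc[r / 2];
    }
  }
  return out;
}

static mat up_bwd(const mat& dY, int H, int W) {
  const int C = dY.n_cols, H2 = 2 * H, W2 = 2 * W;
  mat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* s = dY.colptr(c);
    double* d = dX.colptr(c);
    for (int cc = 0; cc < W2; ++cc) {
      const double* sc = s + cc * H2;
      double* dc = d + (cc / 2) * H;
      for (int r = 0; r < H2; ++r) dc[r / 2] += sc[r];
    }
  }
  return dX;
}

// One full pass.  ximg is the zero-padded frame (H x W, multiples of 8);
// ymask, when given, is the H0 x W0 target on the valid region.  Returns the
// probability map on the valid region plus, with a target, the loss and the
// parameter gradients (names matching model$params).
// [[Rcpp::export]]
List unet_pass_cpp(List params, const arma::mat& ximg,
                   Nullable<NumericMatrix> ymask, int H0, int W0) {
  const int H = ximg.n_rows, W = ximg.n_cols;
  const mat W1 = params["W1"], W2 = params["W2"], W3 = params["W3"],
            W4 = params["W4"], W5 = params["W5"], W6 = params["W6"],
            W7 = params["W7"], W8 = params["W8"];
  const arma::rowvec b1 = as<arma::rowvec>(params["b1"]),
                     b2 = as<arma::rowvec>(params["b2"]),
                     b3 = as<arma::rowvec>(params["b3"]),
                     b4 = as<arma::rowvec>(params["b4"]),
                     b5 = as<arma::rowvec>(params["b5"]),
                     b6 = as<arma::rowvec>(params["b6"]),
                     b7 = as<arma::rowvec>(params["b7"]),
                     b8 = as<arma::rowvec>(params["b8"]);
  const int c1 = W1.n_cols, c2 = W2.n_cols, c3 = W3.n_cols;

  mat X0(const_cast<double*>(ximg.memptr()), H * W, 1, false, true);

  ConvCache cc1, cc2, cc3, cc4, cc5, cc6;
  arma::umat am1, am2, am3;
  mat A1 = conv_relu(X0, H, W, W1, b1, cc1);
  mat P1 = pool_fwd(A1, H, W, am1);
  mat A2 = conv_relu(P1, H / 2, W / 2, W2, b2, cc2);
  mat P2 = pool_fwd(A2, H / 2, W / 2, am2);
  mat A3 = conv_relu(P2, H / 4, W / 4, W3, b3, cc3);
  mat P3 = pool_fwd(A3, H / 4, W / 4, am3);
  mat A4 = conv_relu(P3, H / 8, W / 8, W4, b4, cc4);

  mat U3 = up_fwd(A4, H / 8, W / 8);
  mat K5 = arma::join_rows(U3, A3);
  mat A5 = conv_relu(K5, H / 4, W / 4, W5, b5, cc5);
  mat U2 = up_fwd(A5, H / 4, W / 4);
  mat K6 = arma::join_rows(U2, A2);
  mat A6 = conv_relu(K6, H / 2, W / 2, W6, b6, cc6);
  mat U1 = up_fwd(A6, H / 2, W / 2);
  mat K7 = arma::join_rows(U1, A1);
  mat Z7 = K7 * W7;
  Z7.each_row() += b7;
  mat A7 = Z7;
  A7.for_each([](double& v) { if (v < 0) v = 0; });
  mat Z8 = A7 * W8;
  Z8 += b8(0);
  mat prob_full(H, W);
  {
    double* pp = prob_full.memptr();
    const double* zp = Z8.memptr();
    for (int i = 0; i < H * W; ++i) pp[i] = 1.0 / (1.0 + std::exp(-zp[i]));
  }
  NumericMatrix prob_out(H0, W0);
  for (int c = 0; c < W0; ++c)
    for (int r = 0; r < H0; ++r) prob_out(r, c) = prob_full(r, c);
  if (ymask.isNull())
    return List::create(_["prob"] = prob_out);

  // ---- loss + gradient of the mean BCE over the valid region ----
  NumericMatrix ym(ymask);
  const double eps = 1e-7;
  const double nval = (double)H0 * W0;
  double loss = 0;
  mat dz8(H * W, 1, arma::fill::zeros);
  for (int c = 0; c < W0; ++c) {
    for (int r = 0; r < H0; ++r) {
      const double p0 = prob_full(r, c);
      const double p = std::min(std::max(p0, eps), 1.0 - eps);
      const double y = ym(r, c);
      loss -= y * std::log(p) + (1 - y) * std::log(1 - p);
      dz8(r + c * H, 0) = (p0 - y) / nval;
    }
  }
  loss /= nval;

  List g;
  g["W8"] = A7.t() * dz8;
  g["b8"] = arma::accu(dz8);
  mat dA7 = dz8 * W8.t();
  mat dZ7 = dA7 % (Z7 > 0);
  g["W7"] = K7.t() * dZ7;
  g["b7"] = arma::sum(dZ7, 0).t();
  mat dK7 = dZ7 * W7.t();
  mat dU1 = dK7.cols(0, c1 - 1);
  mat dA1skip = dK7.cols(c1, 2 * c1 - 1);

  mat dW; arma::rowvec db;
  mat dA6 = up_bwd(dU1, H / 2, W / 2);
  mat dK6 = conv_relu_bwd(dA6, cc6, W6, H / 2, W / 2, 2 * c2, dW, db);
  g["W6"] = dW; g["b6"] = db.t();
  mat dU2 = dK6.cols(0, c2 - 1);
  mat dA2skip = dK6.cols(c2, 2 * c2 - 1);
  mat dA5 = up_bwd(dU2, H / 4, W / 4);
  mat dK5 = conv_relu_bwd(dA5, cc5, W5, H / 4, W / 4, 2 * c3, dW, db);
  g["W5"] = dW; g["b5"] = db.t();
  mat dU3 = dK5.cols(0, c3 - 1);
  mat dA3skip = dK5.cols(c3, 2 * c3 - 1);
  mat dA4 = up_bwd(dU3, H / 8, W / 8);
  mat dP3 = conv_relu_bwd(dA4, cc4, W4, H / 8, W / 8, c3, dW, db);
  g["W4"] = dW; g["b4"] = db.t();
  mat dA3 = pool_bwd(dP3, am3, H / 4, W / 4) + dA3skip;
  mat dP2 = conv_relu_bwd(dA3, cc3, W3, H / 4, W / 4, c2, dW, db);
  g["W3"] = dW; g["b3"] = db.t();
  mat dA2 = pool_bwd(dP2, am2, H / 2, W / 2) + dA2skip;
  mat dP1 = conv_relu_bwd(dA2, cc2, W2, H / 2, W / 2, c1, dW, db);
  g["W2"] = dW; g["b2"] = db.t();
  mat dA1 = pool_bwd(dP1, am1, H, W) + dA1skip;
  conv_relu_bwd(dA1, cc1, W1, H, W, 1, dW, db);
  g["W1"] = dW; g["b1"] = db.t();

  return List::create(_["prob"] = prob_out, _["loss"] = loss,
                      _["grads"] = g);
}
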