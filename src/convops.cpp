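#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Activations are stored as (H*W) x C matrices, pixels in R's column-major
// order: linear index = r + c*H (0-based).  Convolution weight matrices are
// (9*Cin) x Cout with row index c*9 + (dc+1)*3 + (dr+1), so forward conv is
// a single GEMM on the im2col expansion.

// [[Rcpp::export]]
NumericMatrix im2col3(const NumericMatrix& X, int H, int W) {
  const int C = X.ncol();
  NumericMatrix out(H * W, 9 * C); // zero-initialised: zero padding for free
  int k = 0;
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        for (int cc = 0; cc < W; ++cc) {
          const int sc = cc + dc;
          if (sc < 0 || sc >= W) continue;
          const double* src = &X(0, c);
          double* dst = &out(0, k);
          for (int rr = 0; rr < H; ++rr) {
            const int sr = rr + dr;
            if (sr < 0 || sr >= H) continue;
            dst[rr + cc * H] = src[sr + sc * H];
          }
        }
        ++k;
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add patch-gradient columns back to pixels.
// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& dXcol, int H, int W, int C) {
  NumericMatrix dX(H * W, C);
  int k = 0;
  for (int c = 0; c < C; ++c) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        for (int cc = 0; cc < W; ++cc) {
          const int sc = cc + dc;
          if (sc < 0 || sc >= W) continue;
          const double* src = &dXcol(0, k);
          double* dst = &dX(0, c);
          for (int rr = 0; rr < H; ++rr) {
            const int sr = rr + dr;
            if (sr < 0 || sr >= H) continue;
            dst[sr + sc * H] += src[rr + cc * H];
          }
        }
        ++k;
      }
    }
  }
  return dX;
}

// 8-connected labelling of a binary H x W matrix.  Labels are assigned in
// raster scan order of first contact; callers re-order components as needed.
// [[Rcpp::export]]
IntegerMatrix label_components8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int dc = -1; dc <= 1; ++dc) {
          const int nc = pc + dc;
          if (nc < 0 || nc >= W) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int nr = pr + dr;
            if (nr < 0 || nr >= H) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Direct 3x3 same-padding convolution, fused bias + optional ReLU.
// Same weight layout as the im2col path: row index c*9 + (dc+1)*3 + (dr+1).
// [[Rcpp::export]]
NumericMatrix conv3_fwd(const NumericMatrix& X, const NumericMatrix& Wm,
                        const NumericVector& b, int H, int W, bool relu) {
  const int C = X.ncol(), F = Wm.ncol(), n = H * W;
  NumericMatrix A(n, F);
  for (int f = 0; f < F; ++f) {
    double* ap = &A(0, f);
    const double bf = b[f];
    for (int i = 0; i < n; ++i) ap[i] = bf;
  }
  for (int ci = 0; ci < C; ++ci) {
    const double* xb = &X(0, ci);
    for (int dc = -1; dc <= 1; ++dc) {
      const int c0 = dc < 0 ? 1 : 0, c1 = dc > 0 ? W - 1 : W;
      for (int dr = -1; dr <= 1; ++dr) {
        const int r0 = dr < 0 ? 1 : 0, r1 = dr > 0 ? H - 1 : H;
        const int krow = ci * 9 + (dc + 1) * 3 + (dr + 1);
        for (int f = 0; f < F; ++f) {
          const double w = Wm(krow, f);
          if (w == 0.0) continue;
          double* ab = &A(0, f);
          for (int c = c0; c < c1; ++c) {
            const double* xp = xb + (c + dc) * H + dr;
            double* ap = ab + c * H;
            for (int r = r0; r < r1; ++r) ap[r] += w * xp[r];
          }
        }
      }
    }
  }
  if (relu) {
    double* ap = A.begin();
    const R_xlen_t tot = (R_xlen_t)n * F;
    for (R_xlen_t i = 0; i < tot; ++i) if (ap[i] < 0) ap[i] = 0;
  }
  return A;
}

// Backward pass of conv3_fwd.  A is the forward output (post-ReLU when relu
// was set); dA the gradient at A.  Returns dW, db, dX.
// [[Rcpp::export]]
List conv3_bwd(const NumericMatrix& X, const NumericMatrix& A,
               const NumericMatrix& dA, const NumericMatrix& Wm,
               int H, int W, bool relu) {
  const int C = X.ncol(), F = Wm.ncol(), n = H * W;
  NumericMatrix dZ(n, F);
  {
    const double* aap = A.begin();
    const double* dap = dA.begin();
    double* dzp = dZ.begin();
    const R_xlen_t tot = (R_xlen_t)n * F;
    if (relu) {
      for (R_xlen_t i = 0; i < tot; ++i) dzp[i] = aap[i] > 0 ? dap[i] : 0.0;
    } else {
      for (R_xlen_t i = 0; i < tot; ++i) dzp[i] = dap[i];
    }
  }
  NumericMatrix dW(9 * C, F);
  NumericVector db(F);
  NumericMatrix dX(n, C);
  for (int f = 0; f < F; ++f) {
    const double* dzp = &dZ(0, f);
    double s = 0;
    for (int i = 0; i < n; ++i) s += dzp[i];
    db[f] = s;
  }
  for (int ci = 0; ci < C; ++ci) {
    const double* xb = &X(0, ci);
    double* dxb = &dX(0, ci);
    for (int dc = -1; dc <= 1; ++dc) {
      const int c0 = dc < 0 ? 1 : 0, c1 = dc > 0 ? W - 1 : W;
      for (int dr = -1; dr <= 1; ++dr) {
        const int r0 = dr < 0 ? 1 : 0, r1 = dr > 0 ? H - 1 : H;
        const int krow = ci * 9 + (dc + 1) * 3 + (dr + 1);
        for (int f = 0; f < F; ++f) {
          const double w = Wm(krow, f);
          const double* dzb = &dZ(0, f);
          double acc = 0;
          for (int c = c0; c < c1; ++c) {
            const double* xp = xb + (c + dc) * H + dr;
            const double* dzp = dzb + c * H;
            double* dxp = dxb + (c + dc) * H + dr;
            for (int r = r0; r < r1; ++r) {
              acc += xp[r] * dzp[r];
              dxp[r] += w * dzp[r];
            }
          }
          dW(krow, f) = acc;
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
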