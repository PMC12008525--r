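#include <Rcpp.h>
using namespace Rcpp;

// 3x3 same-padding im2col / col2im for (H, W, C) arrays stored in R's
// column-major layout: x[h, w, c] lives at h + H*w + H*W*c (0-based).
// The unfolded matrix has one row per spatial cell (h + H*w) and columns
// ordered as (dh + 3*dw) + 9*c with dh, dw in {-1, 0, 1} mapped to {0, 1, 2}.
// Out-of-range taps read as zero, so convolution = im2col %*% W with
// W of shape (9*C_in, C_out).

// [[Rcpp::export]]
NumericMatrix im2col3_cpp(const NumericVector& x, int H, int W, int C) {
  NumericMatrix out(H * W, 9 * C);
  for (int c = 0; c < C; ++c) {
    const int xoff = H * W * c;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = (dh + 1) + 3 * (dw + 1) + 9 * c;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh;
            if (sh < 0 || sh >= H) continue;
            out(h + H * w, col) = x[sh + H * sw + xoff];
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter-add the unfolded gradient back to (H, W, C).

// [[Rcpp::export]]
NumericVector col2im3_cpp(const NumericMatrix& dcol, int H, int W, int C) {
  NumericVector dx(H * W * C);
  for (int c = 0; c < C; ++c) {
    const int xoff = H * W * c;
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = (dh + 1) + 3 * (dw + 1) + 9 * c;
        for (int w = 0; w < W; ++w) {
          const int sw = w + dw;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int sh = h + dh;
            if (sh < 0 || sh >= H) continue;
            dx[sh + H * sw + xoff] += dcol(h + H * w, col);
          }
        }
      }
    }
  }
  return dx;
}
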