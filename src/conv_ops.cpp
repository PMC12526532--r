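#include <Rcpp.h>
using namespace Rcpp;

// Tensors are R arrays with dim (H, W, C, N), column-major.
// im2col produces an (M x K) matrix with row m = oh + OH*(ow + OW*n) and
// column r = i + kh*(j + kw*c), so the inner oh loop writes contiguously.
// pad_mode: 0 = zero, 1 = mirror reflection without border repeat.

static inline int reflect_idx(int p, int n) {
  // valid for |overhang| < n; degenerate 1-wide axes clamp to 0
  if (n == 1) return 0;
  if (p < 0) return -p;
  if (p >= n) return 2 * n - 2 - p;
  return p;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int pad_mode) {
  const int OH = (H + 2 * ph - kh) / sh + 1;
  const int OW = (W + 2 * pw - kw) / sw + 1;
  const int K = kh * kw * C;
  const R_xlen_t M = (R_xlen_t)OH * OW * N;
  NumericMatrix out(M, K);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        double* ocol = op + (R_xlen_t)r * M;
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + ((R_xlen_t)n * C + c) * H * W;
          for (int ow = 0; ow < OW; ++ow) {
            int wsrc = ow * sw - pw + j;
            bool wout = (wsrc < 0 || wsrc >= W);
            if (wout && pad_mode == 1) { wsrc = reflect_idx(wsrc, W); wout = false; }
            double* od = ocol + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n);
            if (wout) {
              for (int oh = 0; oh < OH; ++oh) od[oh] = 0.0;
              continue;
            }
            const double* xcol = xc + (R_xlen_t)H * wsrc;
            if (pad_mode == 1) {
              for (int oh = 0; oh < OH; ++oh)
                od[oh] = xcol[reflect_idx(oh * sh - ph + i, H)];
            } else {
              for (int oh = 0; oh < OH; ++oh) {
                const int hsrc = oh * sh - ph + i;
                od[oh] = (hsrc < 0 || hsrc >= H) ? 0.0 : xcol[hsrc];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C, int N,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int pad_mode) {
  const int OH = (H + 2 * ph - kh) / sh + 1;
  const int OW = (W + 2 * pw - kw) / sw + 1;
  const R_xlen_t M = (R_xlen_t)OH * OW * N;
  NumericVector dx((R_xlen_t)H * W * C * N);
  const double* cp = cols.begin();
  double* dp = dx.begin();
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        const int r = i + kh * (j + kw * c);
        const double* ccol = cp + (R_xlen_t)r * M;
        for (int n = 0; n < N; ++n) {
          double* dc = dp + ((R_xlen_t)n * C + c) * H * W;
          for (int ow = 0; ow < OW; ++ow) {
            int wsrc = ow * sw - pw + j;
            bool wout = (wsrc < 0 || wsrc >= W);
            if (wout && pad_mode == 1) { wsrc = reflect_idx(wsrc, W); wout = false; }
            if (wout) continue;
            const double* cd = ccol + (R_xlen_t)OH * (ow + (R_xlen_t)OW * n);
            double* dcol = dc + (R_xlen_t)H * wsrc;
            for (int oh = 0; oh < OH; ++oh) {
              int hsrc = oh * sh - ph + i;
              bool hout = (hsrc < 0 || hsrc >= H);
              if (hout && pad_mode == 1) { hsrc = reflect_idx(hsrc, H); hout = false; }
              if (hout) continue;
              dcol[hsrc] += cd[oh];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  return dx;
}

// Depth-wise convolution: one kh x kw kernel per channel, weight dim (kh,kw,C).
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, NumericVector w, NumericVector b,
                             int H, int W, int C, int N,
                             int kh, int kw, int sh, int sw,
                             int ph, int pw, int pad_mode) {
  const int OH = (H + 2 * ph - kh) / sh + 1;
  const int OW = (W + 2 * pw - kw) / sw + 1;
  NumericVector y((R_xlen_t)OH * OW * C * N);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* yp = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)n * C + c) * H * W;
      const double* wc = wp + (R_xlen_t)c * kh * kw;
      double* yc = yp + ((R_xlen_t)n * C + c) * OH * OW;
      const double bc = b[c];
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          double acc = bc;
          for (int j = 0; j < kw; ++j) {
            int wsrc = ow * sw - pw + j;
            bool wout = (wsrc < 0 || wsrc >= W);
            if (wout && pad_mode == 1) { wsrc = reflect_idx(wsrc, W); wout = false; }
            if (wout) continue;
            for (int i = 0; i < kh; ++i) {
              int hsrc = oh * sh - ph + i;
              bool hout = (hsrc < 0 || hsrc >= H);
              if (hout && pad_mode == 1) { hsrc = reflect_idx(hsrc, H); hout = false; }
              if (hout) continue;
              acc += wc[i + kh * j] * xc[hsrc + (R_xlen_t)H * wsrc];
            }
          }
          yc[oh + (R_xlen_t)OH * ow] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(OH, OW, C, N);
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int H, int W, int C, int N,
                    int kh, int kw, int sh, int sw,
                    int ph, int pw, int pad_mode) {
  const int OH = (H + 2 * ph - kh) / sh + 1;
  const int OW = (W + 2 * pw - kw) / sw + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)kh * kw * C);
  NumericVector db(C);
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = dy.begin();
  double* dxp = dx.begin();
  double* dwp = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + ((R_xlen_t)n * C + c) * H * W;
      const double* wc = wp + (R_xlen_t)c * kh * kw;
      const double* gc = gp + ((R_xlen_t)n * C + c) * OH * OW;
      double* dxc = dxp + ((R_xlen_t)n * C + c) * H * W;
      double* dwc = dwp + (R_xlen_t)c * kh * kw;
      double accb = 0.0;
      for (int ow = 0; ow < OW; ++ow) {
        for (int oh = 0; oh < OH; ++oh) {
          const double g = gc[oh + (R_xlen_t)OH * ow];
          accb += g;
          for (int j = 0; j < kw; ++j) {
            int wsrc = ow * sw - pw + j;
            bool wout = (wsrc < 0 || wsrc >= W);
            if (wout && pad_mode == 1) { wsrc = reflect_idx(wsrc, W); wout = false; }
            if (wout) continue;
            for (int i = 0; i < kh; ++i) {
              int hsrc = oh * sh - ph + i;
              bool hout = (hsrc < 0 || hsrc >= H);
              if (hout && pad_mode == 1) { hsrc = reflect_idx(hsrc, H); hout = false; }
              if (hout) continue;
              dwc[i + kh * j] += g * xc[hsrc + (R_xlen_t)H * wsrc];
              dxc[hsrc + (R_xlen_t)H * wsrc] += g * wc[i + kh * j];
            }
          }
        }
      }
      db[c] += accb;
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  dw.attr("dim") = IntegerVector::create(kh, kw, C);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}
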