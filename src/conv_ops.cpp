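#include <Rcpp.h>
using namespace Rcpp;

// Layout convention: an activation tensor of N slices of size H x W with C
// channels is a (H*W*N) x C matrix, column-major, with row index
// r = h + H*w + H*W*n. Convolution weights are (k*k*C_in, C_out) matrices so
// conv = im2col(x) %*% W + b; 1x1 convolutions reduce to plain matmul.

// [[Rcpp::export]]
NumericMatrix im2col_cm(NumericMatrix m, int H, int W, int N, int k) {
  int pad = (k - 1) / 2;
  int C = m.ncol();
  R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix out(rows, k * k * C);
  const double *pm = m.begin();
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    const double *src_ch = pm + (R_xlen_t)c * rows;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        double *dst0 = po + ((R_xlen_t)(c * k * k + kw * k + kh)) * rows;
        for (int n = 0; n < N; ++n) {
          const double *src_img = src_ch + (R_xlen_t)n * H * W;
          double *dst_img = dst0 + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            int sw = w + kw - pad;
            double *dst = dst_img + (R_xlen_t)w * H;
            if (sw < 0 || sw >= W) {
              std::fill(dst, dst + H, 0.0);
            } else {
              const double *src = src_img + (R_xlen_t)sw * H;
              int sh0 = kh - pad;
              int h0 = std::max(0, -sh0), h1 = std::min(H, H - sh0);
              for (int h = 0; h < h0; ++h) dst[h] = 0.0;
              for (int h = h0; h < h1; ++h) dst[h] = src[h + sh0];
              for (int h = h1; h < H; ++h) dst[h] = 0.0;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cm: scatter-add columns back onto the image grid.
// [[Rcpp::export]]
NumericMatrix col2im_cm(NumericMatrix cols, int H, int W, int N, int k,
                        int C) {
  int pad = (k - 1) / 2;
  R_xlen_t rows = (R_xlen_t)H * W * N;
  NumericMatrix x(rows, C);
  double *px = x.begin();
  const double *pc = cols.begin();
  for (int c = 0; c < C; ++c) {
    double *dst_ch = px + (R_xlen_t)c * rows;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const double *src0 = pc + ((R_xlen_t)(c * k * k + kw * k + kh)) * rows;
        for (int n = 0; n < N; ++n) {
          double *dst_img = dst_ch + (R_xlen_t)n * H * W;
          const double *src_img = src0 + (R_xlen_t)n * H * W;
          for (int w = 0; w < W; ++w) {
            int sw = w + kw - pad;
            if (sw < 0 || sw >= W) continue;
            double *dst = dst_img + (R_xlen_t)sw * H;
            const double *src = src_img + (R_xlen_t)w * H;
            int sh0 = kh - pad;
            int h0 = std::max(0, -sh0), h1 = std::min(H, H - sh0);
            for (int h = h0; h < h1; ++h) dst[h + sh0] += src[h];
          }
        }
      }
    }
  }
  return x;
}

// 2x2 max pooling, stride 2, per channel; records 1-based flat indices into
// the input matrix for unpooling.
// [[Rcpp::export]]
List maxpool2_cm(NumericMatrix m, int H, int W, int N) {
  int C = m.ncol();
  int Ho = H / 2, Wo = W / 2;
  R_xlen_t rows_in = (R_xlen_t)H * W * N;
  R_xlen_t rows_out = (R_xlen_t)Ho * Wo * N;
  NumericMatrix y(rows_out, C);
  IntegerMatrix idx(rows_out, C);
  const double *pm = m.begin();
  double *py = y.begin();
  int *pi = idx.begin();
  for (int c = 0; c < C; ++c) {
    const double *src_ch = pm + (R_xlen_t)c * rows_in;
    double *y_ch = py + (R_xlen_t)c * rows_out;
    int *i_ch = pi + (R_xlen_t)c * rows_out;
    for (int n = 0; n < N; ++n) {
      const double *img = src_ch + (R_xlen_t)n * H * W;
      double *yo = y_ch + (R_xlen_t)n * Ho * Wo;
      int *io = i_ch + (R_xlen_t)n * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t base = (R_xlen_t)(2 * w) * H + 2 * h;
          R_xlen_t cand[4] = {base, base + 1, base + H, base + H + 1};
          R_xlen_t best = cand[0];
          double bv = img[cand[0]];
          for (int q = 1; q < 4; ++q)
            if (img[cand[q]] > bv) { bv = img[cand[q]]; best = cand[q]; }
          yo[(R_xlen_t)w * Ho + h] = bv;
          io[(R_xlen_t)w * Ho + h] =
            (int)((R_xlen_t)c * rows_in + (R_xlen_t)n * H * W + best) + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Surface voxels of a 3D binary mask: foreground with a 6-neighbour
// background (or out-of-bounds) face.
// [[Rcpp::export]]
LogicalVector surface6_nat(LogicalVector mask, int nx, int ny, int nz) {
  LogicalVector out((R_xlen_t)nx * ny * nz);
  const int *m = LOGICAL(mask);
  int *o = LOGICAL(out);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t i = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
        if (!m[i]) { o[i] = FALSE; continue; }
        bool border =
          (x == 0 || !m[i - 1]) || (x == nx - 1 || !m[i + 1]) ||
          (y == 0 || !m[i - nx]) || (y == ny - 1 || !m[i + nx]) ||
          (z == 0 || !m[i - (R_xlen_t)nx * ny]) ||
          (z == nz - 1 || !m[i + (R_xlen_t)nx * ny]);
        o[i] = border;
      }
  return out;
}

// Directed nearest-surface distances: for each point in A (rows of amat, mm
// coordinates) the distance to the closest point in B.
// [[Rcpp::export]]
NumericVector nn_dist_nat(NumericMatrix amat, NumericMatrix bmat) {
  int na = amat.nrow(), nb = bmat.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double ax = amat(i, 0), ay = amat(i, 1), az = amat(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double dx = ax - bmat(j, 0), dy = ay - bmat(j, 1), dz = az - bmat(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
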