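// 3D convolution primitives used by the segmentation network.
//
// Tensor layout (shared with the R side): a feature map is an R array with
// dim = c(nx, ny, nz, nc) — x (width) fastest, then y (height), z (depth),
// channel. Convolution weights are a matrix with k^3 * nc_in rows (kx fastest,
// then ky, kz, then input channel) and nc_out columns, so the forward pass is
// one GEMM per column chunk: out = t(W) %*% im2col(x).
//
// Compute happens in single precision (im2col + sgemm), the convention of
// CPU deep-learning kernels: it halves the memory traffic that dominates the
// large, shallow-channel layers. Interior columns (no padding clamp anywhere
// in their receptive field) take a branch-free memcpy fast path.
//
// All kernels are cubic (k x k x k) with isotropic stride and zero padding.
// The transposed convolution is specialised to kernel 2, stride 2 (the only
// variant the network uses); its 2x2x2 output blocks do not overlap, so both
// passes reduce to a single GEMM plus a gather/scatter.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

inline int out_extent(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

const int CHUNK = 4096;

struct ConvGeom {
  int nx, ny, nz, nc, k, stride, pad, ox, oy, oz;
  int k2, k3, nvox_in;
};

ConvGeom make_geom(const IntegerVector& xdim, int k, int stride, int pad) {
  ConvGeom g;
  g.nx = xdim[0]; g.ny = xdim[1]; g.nz = xdim[2]; g.nc = xdim[3];
  g.k = k; g.stride = stride; g.pad = pad;
  g.ox = out_extent(g.nx, k, stride, pad);
  g.oy = out_extent(g.ny, k, stride, pad);
  g.oz = out_extent(g.nz, k, stride, pad);
  g.k2 = k * k; g.k3 = g.k2 * k;
  g.nvox_in = g.nx * g.ny * g.nz;
  return g;
}

// Fill `cols` (rows x nchunk) with im2col columns for output voxels
// [o0, o0 + nchunk). Out-of-bounds taps are zero.
void im2col_chunk(const float* x, const ConvGeom& g,
                  int o0, int nchunk, arma::fmat& cols) {
  const int k = g.k;
  for (int j = 0; j < nchunk; ++j) {
    int o = o0 + j;
    int oxi = o % g.ox;
    int oyi = (o / g.ox) % g.oy;
    int ozi = o / (g.ox * g.oy);
    int ix0 = oxi * g.stride - g.pad;
    int iy0 = oyi * g.stride - g.pad;
    int iz0 = ozi * g.stride - g.pad;
    float* col = cols.colptr(j);
    bool interior = ix0 >= 0 && ix0 + k <= g.nx &&
                    iy0 >= 0 && iy0 + k <= g.ny &&
                    iz0 >= 0 && iz0 + k <= g.nz;
    if (interior) {
      float* dst = col;
      if (k == 3) {
        for (int c = 0; c < g.nc; ++c) {
          const float* xc = x + (std::size_t)c * g.nvox_in;
          for (int kz = 0; kz < 3; ++kz) {
            const float* xz = xc + (std::size_t)(iz0 + kz) * g.ny * g.nx + ix0;
            for (int ky = 0; ky < 3; ++ky) {
              const float* s = xz + (std::size_t)(iy0 + ky) * g.nx;
              dst[0] = s[0]; dst[1] = s[1]; dst[2] = s[2];
              dst += 3;
            }
          }
        }
      } else {
        for (int c = 0; c < g.nc; ++c) {
          const float* xc = x + (std::size_t)c * g.nvox_in;
          for (int kz = 0; kz < k; ++kz) {
            const float* xz = xc + (std::size_t)(iz0 + kz) * g.ny * g.nx + ix0;
            for (int ky = 0; ky < k; ++ky) {
              std::memcpy(dst, xz + (std::size_t)(iy0 + ky) * g.nx,
                          k * sizeof(float));
              dst += k;
            }
          }
        }
      }
    } else {
      std::memset(col, 0, cols.n_rows * sizeof(float));
      for (int c = 0; c < g.nc; ++c) {
        const float* xc = x + (std::size_t)c * g.nvox_in;
        for (int kz = 0; kz < k; ++kz) {
          int iz = iz0 + kz;
          if (iz < 0 || iz >= g.nz) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = iy0 + ky;
            if (iy < 0 || iy >= g.ny) continue;
            int rbase = c * g.k3 + kz * g.k2 + ky * k;
            const float* xrow = xc + (std::size_t)(iz * g.ny + iy) * g.nx;
            for (int kx = 0; kx < k; ++kx) {
              int ixp = ix0 + kx;
              if (ixp < 0 || ixp >= g.nx) continue;
              col[rbase + kx] = xrow[ixp];
            }
          }
        }
      }
    }
  }
}

// Scatter-add the columns back (adjoint of im2col_chunk).
void col2im_chunk(float* gx, const ConvGeom& g,
                  int o0, int nchunk, const arma::fmat& cols) {
  const int k = g.k;
  for (int j = 0; j < nchunk; ++j) {
    int o = o0 + j;
    int oxi = o % g.ox;
    int oyi = (o / g.ox) % g.oy;
    int ozi = o / (g.ox * g.oy);
    int ix0 = oxi * g.stride - g.pad;
    int iy0 = oyi * g.stride - g.pad;
    int iz0 = ozi * g.stride - g.pad;
    const float* col = cols.colptr(j);
    bool interior = ix0 >= 0 && ix0 + k <= g.nx &&
                    iy0 >= 0 && iy0 + k <= g.ny &&
                    iz0 >= 0 && iz0 + k <= g.nz;
    if (interior) {
      const float* src = col;
      if (k == 3) {
        for (int c = 0; c < g.nc; ++c) {
          float* gc = gx + (std::size_t)c * g.nvox_in;
          for (int kz = 0; kz < 3; ++kz) {
            float* gz = gc + (std::size_t)(iz0 + kz) * g.ny * g.nx + ix0;
            for (int ky = 0; ky < 3; ++ky) {
              float* grow = gz + (std::size_t)(iy0 + ky) * g.nx;
              grow[0] += src[0]; grow[1] += src[1]; grow[2] += src[2];
              src += 3;
            }
          }
        }
      } else {
        for (int c = 0; c < g.nc; ++c) {
          float* gc = gx + (std::size_t)c * g.nvox_in;
          for (int kz = 0; kz < k; ++kz) {
            float* gz = gc + (std::size_t)(iz0 + kz) * g.ny * g.nx + ix0;
            for (int ky = 0; ky < k; ++ky) {
              float* grow = gz + (std::size_t)(iy0 + ky) * g.nx;
              for (int kx = 0; kx < k; ++kx) grow[kx] += src[kx];
              src += k;
            }
          }
        }
      }
    } else {
      for (int c = 0; c < g.nc; ++c) {
        float* gc = gx + (std::size_t)c * g.nvox_in;
        for (int kz = 0; kz < k; ++kz) {
          int iz = iz0 + kz;
          if (iz < 0 || iz >= g.nz) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = iy0 + ky;
            if (iy < 0 || iy >= g.ny) continue;
            int rbase = c * g.k3 + kz * g.k2 + ky * k;
            float* grow = gc + (std::size_t)(iz * g.ny + iy) * g.nx;
            for (int kx = 0; kx < k; ++kx) {
              int ixp = ix0 + kx;
              if (ixp < 0 || ixp >= g.nx) continue;
              grow[ixp] += col[rbase + kx];
            }
          }
        }
      }
    }
  }
}

arma::fvec to_float(const NumericVector& x) {
  arma::fvec out(x.size());
  const double* src = x.begin();
  float* dst = out.memptr();
  for (R_xlen_t i = 0; i < x.size(); ++i) dst[i] = (float)src[i];
  return out;
}

arma::fmat to_fmat(const NumericMatrix& x) {
  arma::fmat out(x.nrow(), x.ncol());
  std::copy(x.begin(), x.end(), out.begin());
  return out;
}

} // namespace

// [[Rcpp::export(name = ".conv3d_forward_cpp")]]
NumericVector conv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                 NumericMatrix w, NumericVector bias,
                                 int k, int stride, int pad) {
  ConvGeom g = make_geom(xdim, k, stride, pad);
  int rows = g.k3 * g.nc;
  if (w.nrow() != rows)
    stop("weight rows (%d) do not match k^3 * n_in (%d)", w.nrow(), rows);
  int cout = w.ncol();
  if (g.ox < 1 || g.oy < 1 || g.oz < 1)
    stop("spatial extent collapses below 1 (input %dx%dx%d, k=%d, stride=%d)",
         g.nx, g.ny, g.nz, k, stride);
  int novox = g.ox * g.oy * g.oz;

  arma::fvec xf = to_float(x);
  arma::fmat W = to_fmat(w);
  NumericVector out((std::size_t)novox * cout);
  out.attr("dim") = IntegerVector::create(g.ox, g.oy, g.oz, cout);
  arma::fmat cols(rows, std::min(novox, CHUNK));
  double* op = out.begin();

  for (int o0 = 0; o0 < novox; o0 += CHUNK) {
    int nchunk = std::min(CHUNK, novox - o0);
    arma::fmat cview = cols.cols(0, nchunk - 1);
    im2col_chunk(xf.memptr(), g, o0, nchunk, cview);
    arma::fmat res = W.t() * cview; // cout x nchunk
    for (int ch = 0; ch < cout; ++ch) {
      double* dst = op + (std::size_t)ch * novox + o0;
      const double b = bias[ch];
      for (int j = 0; j < nchunk; ++j) dst[j] = (double)res(ch, j) + b;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward_cpp")]]
List conv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                         NumericMatrix w, NumericVector gout,
                         int k, int stride, int pad, bool need_gx = true) {
  ConvGeom g = make_geom(xdim, k, stride, pad);
  int rows = g.k3 * g.nc;
  int cout = w.ncol();
  int novox = g.ox * g.oy * g.oz;
  if ((R_xlen_t)gout.size() != (R_xlen_t)novox * cout)
    stop("gradient size mismatch");

  arma::fvec xf = to_float(x);
  arma::fmat W = to_fmat(w);
  arma::fvec gxf(need_gx ? (std::size_t)g.nvox_in * g.nc : 1, arma::fill::zeros);
  arma::fmat GW(rows, cout, arma::fill::zeros);
  NumericVector gb(cout);
  arma::fmat cols(rows, std::min(novox, CHUNK));
  arma::fmat gmat(cout, std::min(novox, CHUNK));

  for (int o0 = 0; o0 < novox; o0 += CHUNK) {
    int nchunk = std::min(CHUNK, novox - o0);
    arma::fmat cview = cols.cols(0, nchunk - 1);
    im2col_chunk(xf.memptr(), g, o0, nchunk, cview);
    arma::fmat gview = gmat.cols(0, nchunk - 1);
    for (int ch = 0; ch < cout; ++ch) {
      const double* src = gout.begin() + (std::size_t)ch * novox + o0;
      double acc = 0.0;
      for (int j = 0; j < nchunk; ++j) { gview(ch, j) = (float)src[j]; acc += src[j]; }
      gb[ch] += acc;
    }
    GW += cview * gview.t();
    if (need_gx) {
      arma::fmat gcols = W * gview; // rows x nchunk
      col2im_chunk(gxf.memptr(), g, o0, nchunk, gcols);
    }
  }
  NumericVector gx((std::size_t)(need_gx ? g.nvox_in * g.nc : 0));
  if (need_gx) {
    gx.attr("dim") = xdim;
    for (R_xlen_t i = 0; i < gx.size(); ++i) gx[i] = (double)gxf[i];
  }
  NumericMatrix gwm(rows, cout);
  std::copy(GW.begin(), GW.end(), gwm.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwm, _["gb"] = gb);
}

// Transposed convolution, kernel 2, stride 2 (upsampling by 2 on each axis).
// Weight matrix: nc_in rows, nc_out * 8 columns; column index = ch * 8 + off
// with off = kz * 4 + ky * 2 + kx.
// [[Rcpp::export(name = ".deconv3d_forward_cpp")]]
NumericVector deconv3d_forward_cpp(NumericVector x, IntegerVector xdim,
                                   NumericMatrix w, NumericVector bias) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  if (w.nrow() != nc) stop("weight rows do not match input channels");
  if (w.ncol() % 8 != 0) stop("weight columns must be a multiple of 8");
  int cout = w.ncol() / 8;
  int nvox = nx * ny * nz;
  int Ox = 2 * nx, Oy = 2 * ny, Oz = 2 * nz;
  std::size_t novox = (std::size_t)Ox * Oy * Oz;

  arma::fmat X(nc, nvox);
  const double* xp = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int v = 0; v < nvox; ++v) X(c, v) = (float)xp[(std::size_t)c * nvox + v];
  arma::fmat W = to_fmat(w);
  arma::fmat O = W.t() * X; // (cout*8) x nvox

  NumericVector out(novox * cout);
  out.attr("dim") = IntegerVector::create(Ox, Oy, Oz, cout);
  double* op = out.begin();
  for (int ch = 0; ch < cout; ++ch) {
    double b = bias[ch];
    double* oc = op + (std::size_t)ch * novox;
    for (std::size_t i = 0; i < novox; ++i) oc[i] = b;
    for (int off = 0; off < 8; ++off) {
      int kx = off & 1, ky = (off >> 1) & 1, kz = (off >> 2) & 1;
      const float* row = O.memptr() + (ch * 8 + off); // row-strided
      for (int v = 0; v < nvox; ++v) {
        int ix = v % nx, iy = (v / nx) % ny, iz = v / (nx * ny);
        std::size_t oi = (std::size_t)((2 * iz + kz) * Oy + (2 * iy + ky)) * Ox
                         + (2 * ix + kx);
        oc[oi] += (double)row[(std::size_t)v * O.n_rows];
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".deconv3d_backward_cpp")]]
List deconv3d_backward_cpp(NumericVector x, IntegerVector xdim,
                           NumericMatrix w, NumericVector gout) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2], nc = xdim[3];
  int cout = w.ncol() / 8;
  int nvox = nx * ny * nz;
  int Ox = 2 * nx, Oy = 2 * ny, Oz = 2 * nz;
  std::size_t novox = (std::size_t)Ox * Oy * Oz;
  if (gout.size() != novox * (std::size_t)cout) stop("gradient size mismatch");

  arma::fmat GO(cout * 8, nvox);
  NumericVector gb(cout);
  const double* gp = gout.begin();
  for (int ch = 0; ch < cout; ++ch) {
    const double* gc = gp + (std::size_t)ch * novox;
    double acc = 0.0;
    for (std::size_t i = 0; i < novox; ++i) acc += gc[i];
    gb[ch] = acc;
    for (int off = 0; off < 8; ++off) {
      int kx = off & 1, ky = (off >> 1) & 1, kz = (off >> 2) & 1;
      for (int v = 0; v < nvox; ++v) {
        int ix = v % nx, iy = (v / nx) % ny, iz = v / (nx * ny);
        std::size_t oi = (std::size_t)((2 * iz + kz) * Oy + (2 * iy + ky)) * Ox
                         + (2 * ix + kx);
        GO(ch * 8 + off, v) = (float)gc[oi];
      }
    }
  }
  arma::fmat X(nc, nvox);
  const double* xp = x.begin();
  for (int c = 0; c < nc; ++c)
    for (int v = 0; v < nvox; ++v) X(c, v) = (float)xp[(std::size_t)c * nvox + v];
  arma::fmat W = to_fmat(w);
  arma::fmat GX = W * GO;        // nc x nvox
  arma::fmat GW = X * GO.t();    // nc x (cout*8)

  NumericVector gx((std::size_t)nvox * nc);
  gx.attr("dim") = xdim;
  for (int c = 0; c < nc; ++c) {
    double* dst = gx.begin() + (std::size_t)c * nvox;
    for (int v = 0; v < nvox; ++v) dst[v] = (double)GX(c, v);
  }
  NumericMatrix gwm(nc, cout * 8);
  std::copy(GW.begin(), GW.end(), gwm.begin());
  return List::create(_["gx"] = gx, _["gw"] = gwm, _["gb"] = gb);
}
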