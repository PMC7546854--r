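// Low-level geometry kernels: tent-kernel (bi/trilinear) sampling with the
// border-zero convention, cubic (Keys) interpolation of a coarse control
// lattice to a dense displacement field, and a translation-search NCC helper.
//
// Array convention: volumes are stored column-major with dim (nz, ny, nx);
// linear index = iz + nz*(iy + ny*ix). Coordinates are 0-based with voxel
// centers at integers; x indexes the third array axis, y the second, z the
// first. Point matrices carry columns (x, y, z).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double tent(double t) {
  double a = 1.0 - std::fabs(t);
  return a > 0.0 ? a : 0.0;
}

// [[Rcpp::export]]
NumericVector cppSamplePoints3D(NumericVector src, IntegerVector dims,
                                NumericMatrix pts) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    double acc = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const int iz = z0 + dz;
      if (iz < 0 || iz >= nz) continue;
      const double wz = tent(z - iz);
      if (wz <= 0.0) continue;
      for (int dy = 0; dy <= 1; ++dy) {
        const int iy = y0 + dy;
        if (iy < 0 || iy >= ny) continue;
        const double wy = tent(y - iy);
        if (wy <= 0.0) continue;
        for (int dx = 0; dx <= 1; ++dx) {
          const int ix = x0 + dx;
          if (ix < 0 || ix >= nx) continue;
          const double wx = tent(x - ix);
          if (wx <= 0.0) continue;
          acc += wz * wy * wx * src[iz + nz * (iy + (R_xlen_t)ny * ix)];
        }
      }
    }
    out[i] = acc;
  }
  return out;
}

// Gradient of the sampled values with respect to the point coordinates,
// premultiplied by the upstream gradient dOut. Returns n x 3 (d/dx, d/dy, d/dz).
// [[Rcpp::export]]
NumericMatrix cppSampleGrad3D(NumericVector src, IntegerVector dims,
                              NumericMatrix pts, NumericVector dOut) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n = pts.nrow();
  NumericMatrix g(n, 3);
  for (int i = 0; i < n; ++i) {
    const double up = dOut[i];
    if (up == 0.0) continue;
    const double x = pts(i, 0), y = pts(i, 1), z = pts(i, 2);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
              z0 = (int)std::floor(z);
    double gx = 0.0, gy = 0.0, gz = 0.0;
    for (int dz = 0; dz <= 1; ++dz) {
      const int iz = z0 + dz;
      if (iz < 0 || iz >= nz) continue;
      const double tz = z - iz, wz = tent(tz);
      const double dwz = (std::fabs(tz) < 1.0) ? (tz > 0 ? -1.0 : 1.0) : 0.0;
      for (int dy = 0; dy <= 1; ++dy) {
        const int iy = y0 + dy;
        if (iy < 0 || iy >= ny) continue;
        const double ty = y - iy, wy = tent(ty);
        const double dwy = (std::fabs(ty) < 1.0) ? (ty > 0 ? -1.0 : 1.0) : 0.0;
        for (int dx = 0; dx <= 1; ++dx) {
          const int ix = x0 + dx;
          if (ix < 0 || ix >= nx) continue;
          const double tx = x - ix, wx = tent(tx);
          const double dwx = (std::fabs(tx) < 1.0) ? (tx > 0 ? -1.0 : 1.0) : 0.0;
          const double u = src[iz + nz * (iy + (R_xlen_t)ny * ix)];
          gx += u * dwx * wy * wz;
          gy += u * wx * dwy * wz;
          gz += u * wx * wy * dwz;
        }
      }
    }
    g(i, 0) = up * gx;
    g(i, 1) = up * gy;
    g(i, 2) = up * gz;
  }
  return g;
}

// 2D analogue: src has dim (ny, nx), pts carries columns (x, y).
// [[Rcpp::export]]
NumericVector cppSamplePoints2D(NumericVector src, IntegerVector dims,
                                NumericMatrix pts) {
  const int ny = dims[0], nx = dims[1];
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = pts(i, 0), y = pts(i, 1);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double acc = 0.0;
    for (int dy = 0; dy <= 1; ++dy) {
      const int iy = y0 + dy;
      if (iy < 0 || iy >= ny) continue;
      const double wy = tent(y - iy);
      for (int dx = 0; dx <= 1; ++dx) {
        const int ix = x0 + dx;
        if (ix < 0 || ix >= nx) continue;
        const double wx = tent(x - ix);
        acc += wy * wx * src[iy + (R_xlen_t)ny * ix];
      }
    }
    out[i] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cppSampleGrad2D(NumericVector src, IntegerVector dims,
                              NumericMatrix pts, NumericVector dOut) {
  const int ny = dims[0], nx = dims[1];
  const int n = pts.nrow();
  NumericMatrix g(n, 2);
  for (int i = 0; i < n; ++i) {
    const double up = dOut[i];
    if (up == 0.0) continue;
    const double x = pts(i, 0), y = pts(i, 1);
    const int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
    double gx = 0.0, gy = 0.0;
    for (int dy = 0; dy <= 1; ++dy) {
      const int iy = y0 + dy;
      if (iy < 0 || iy >= ny) continue;
      const double ty = y - iy, wy = tent(ty);
      const double dwy = (std::fabs(ty) < 1.0) ? (ty > 0 ? -1.0 : 1.0) : 0.0;
      for (int dx = 0; dx <= 1; ++dx) {
        const int ix = x0 + dx;
        if (ix < 0 || ix >= nx) continue;
        const double tx = x - ix, wx = tent(tx);
        const double dwx = (std::fabs(tx) < 1.0) ? (tx > 0 ? -1.0 : 1.0) : 0.0;
        const double u = src[iy + (R_xlen_t)ny * ix];
        gx += u * dwx * wy;
        gy += u * wx * dwy;
      }
    }
    g(i, 0) = up * gx;
    g(i, 1) = up * gy;
  }
  return g;
}

// Keys cubic-convolution weights (a = -1/2) for nodes j0-1 .. j0+2.
static inline void keysWeights(double f, double w[4]) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = 0.5 * (-f3 + 2.0 * f2 - f);
  w[1] = 0.5 * (3.0 * f3 - 5.0 * f2 + 2.0);
  w[2] = 0.5 * (-3.0 * f3 + 4.0 * f2 + f);
  w[3] = 0.5 * (f3 - f2);
}

struct AxisTaps {
  std::vector<int> idx;     // n * 4 clamped node indices
  std::vector<double> w;    // n * 4 weights
};

static AxisTaps axisTaps(int n, int nc, double sp) {
  AxisTaps t;
  t.idx.resize((size_t)n * 4);
  t.w.resize((size_t)n * 4);
  for (int i = 0; i < n; ++i) {
    const double u = (double)i / sp;
    int j0 = (int)std::floor(u);
    double f = u - j0;
    double w[4];
    keysWeights(f, w);
    for (int k = 0; k < 4; ++k) {
      int j = j0 - 1 + k;
      if (j < 0) j = 0;
      if (j > nc - 1) j = nc - 1;
      t.idx[(size_t)i * 4 + k] = j;
      t.w[(size_t)i * 4 + k] = w[k];
    }
  }
  return t;
}

// Control lattice (ncz, ncy, ncx, 3) -> dense field (nz, ny, nx, 3); the
// lattice node (a,b,c) sits at voxel coordinate (a*sz, b*sy, c*sx).
// [[Rcpp::export]]
NumericVector cppLatticeToDense(NumericVector lat, IntegerVector latDims,
                                IntegerVector outDims, NumericVector spVox) {
  const int ncz = latDims[0], ncy = latDims[1], ncx = latDims[2];
  const int nz = outDims[0], ny = outDims[1], nx = outDims[2];
  const R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  const R_xlen_t ncvox = (R_xlen_t)ncz * ncy * ncx;
  NumericVector out((R_xlen_t)nvox * 3);
  AxisTaps tz = axisTaps(nz, ncz, spVox[0]);
  AxisTaps ty = axisTaps(ny, ncy, spVox[1]);
  AxisTaps tx = axisTaps(nx, ncx, spVox[2]);
  for (int comp = 0; comp < 3; ++comp) {
    const double *L = &lat[0] + (R_xlen_t)comp * ncvox;
    double *O = &out[0] + (R_xlen_t)comp * nvox;
    for (int ix = 0; ix < nx; ++ix) {
      const int *jx = &tx.idx[(size_t)ix * 4];
      const double *wx = &tx.w[(size_t)ix * 4];
      for (int iy = 0; iy < ny; ++iy) {
        const int *jy = &ty.idx[(size_t)iy * 4];
        const double *wy = &ty.w[(size_t)iy * 4];
        double *col = O + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
        for (int iz = 0; iz < nz; ++iz) {
          const int *jz = &tz.idx[(size_t)iz * 4];
          const double *wz = &tz.w[(size_t)iz * 4];
          double acc = 0.0;
          for (int c = 0; c < 4; ++c) {
            const R_xlen_t offx = (R_xlen_t)ncy * jx[c];
            const double wxc = wx[c];
            if (wxc == 0.0) continue;
            for (int b = 0; b < 4; ++b) {
              const double wyb = wxc * wy[b];
              if (wyb == 0.0) continue;
              const R_xlen_t off = (R_xlen_t)ncz * (jy[b] + offx);
              for (int a = 0; a < 4; ++a)
                acc += wyb * wz[a] * L[jz[a] + off];
            }
          }
          col[iz] = acc;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nz, ny, nx, 3);
  return out;
}

// Adjoint of cppLatticeToDense: scatter a dense-field gradient back to the
// control lattice.
// [[Rcpp::export]]
NumericVector cppDenseGradToLattice(NumericVector dDense, IntegerVector latDims,
                                    IntegerVector outDims, NumericVector spVox) {
  const int ncz = latDims[0], ncy = latDims[1], ncx = latDims[2];
  const int nz = outDims[0], ny = outDims[1], nx = outDims[2];
  const R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  const R_xlen_t ncvox = (R_xlen_t)ncz * ncy * ncx;
  NumericVector out((R_xlen_t)ncvox * 3);
  AxisTaps tz = axisTaps(nz, ncz, spVox[0]);
  AxisTaps ty = axisTaps(ny, ncy, spVox[1]);
  AxisTaps tx = axisTaps(nx, ncx, spVox[2]);
  for (int comp = 0; comp < 3; ++comp) {
    const double *G = &dDense[0] + (R_xlen_t)comp * nvox;
    double *L = &out[0] + (R_xlen_t)comp * ncvox;
    for (int ix = 0; ix < nx; ++ix) {
      const int *jx = &tx.idx[(size_t)ix * 4];
      const double *wx = &tx.w[(size_t)ix * 4];
      for (int iy = 0; iy < ny; ++iy) {
        const int *jy = &ty.idx[(size_t)iy * 4];
        const double *wy = &ty.w[(size_t)iy * 4];
        const double *col = G + (R_xlen_t)nz * (iy + (R_xlen_t)ny * ix);
        for (int iz = 0; iz < nz; ++iz) {
          const double g = col[iz];
          if (g == 0.0) continue;
          const int *jz = &tz.idx[(size_t)iz * 4];
          const double *wz = &tz.w[(size_t)iz * 4];
          for (int c = 0; c < 4; ++c) {
            const double wxc = wx[c];
            if (wxc == 0.0) continue;
            const R_xlen_t offx = (R_xlen_t)ncy * jx[c];
            for (int b = 0; b < 4; ++b) {
              const double wyb = wxc * wy[b];
              if (wyb == 0.0) continue;
              const R_xlen_t off = (R_xlen_t)ncz * (jy[b] + offx);
              for (int a = 0; a < 4; ++a)
                L[jz[a] + off] += g * wyb * wz[a];
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ncz, ncy, ncx, 3);
  return out;
}

// Pearson correlation between the fixed image interior and the moving image
// sampled at interior voxel + shift, for a batch of candidate uniform shifts
// (columns dz, dy, dx in voxels). Used by the global translation initializer.
// [[Rcpp::export]]
NumericVector cppShiftNCC(NumericVector mov, NumericVector fix,
                          IntegerVector dims, NumericMatrix shifts,
                          IntegerVector marginVox) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int mz = marginVox[0], my = marginVox[1], mx = marginVox[2];
  const int ns = shifts.nrow();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const double dz = shifts(s, 0), dy = shifts(s, 1), dx = shifts(s, 2);
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    R_xlen_t cnt = 0;
    for (int ix = mx; ix < nx - mx; ++ix) {
      for (int iy = my; iy < ny - my; ++iy) {
        for (int iz = mz; iz < nz - mz; ++iz) {
          const double x = ix + dx, y = iy + dy, z = iz + dz;
          const int x0 = (int)std::floor(x), y0 = (int)std::floor(y),
                    z0 = (int)std::floor(z);
          double a = 0.0;
          for (int ddz = 0; ddz <= 1; ++ddz) {
            const int jz = z0 + ddz;
            if (jz < 0 || jz >= nz) continue;
            const double wz = tent(z - jz);
            for (int ddy = 0; ddy <= 1; ++ddy) {
              const int jy = y0 + ddy;
              if (jy < 0 || jy >= ny) continue;
              const double wy = tent(y - jy);
              for (int ddx = 0; ddx <= 1; ++ddx) {
                const int jx = x0 + ddx;
                if (jx < 0 || jx >= nx) continue;
                a += wz * wy * tent(x - jx) *
                     mov[jz + nz * (jy + (R_xlen_t)ny * jx)];
              }
            }
          }
          const double b = fix[iz + nz * (iy + (R_xlen_t)ny * ix)];
          sa += a; sb += b; saa += a * a; sbb += b * b; sab += a * b;
          ++cnt;
        }
      }
    }
    const double n = (double)cnt;
    const double cov = sab - sa * sb / n;
    const double va = saa - sa * sa / n;
    const double vb = sbb - sb * sb / n;
    out[s] = (va > 1e-12 && vb > 1e-12) ? cov / std::sqrt(va * vb) : 0.0;
  }
  return out;
}
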