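// Exact anisotropic Euclidean distance transform (Felzenszwalb & Huttenlocher
// lower-envelope-of-parabolas algorithm, applied separably per axis with the
// physical voxel spacing). Input is a seed indicator; output is the distance
// in mm from every voxel to the nearest seed voxel center.
#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform with sample positions i*s.
static void dt1d(const double *f, double *d, int n, double s) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  const double s2 = s * s;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[1] = INF; continue; }
    double sint;
    while (true) {
      const int p = v[k];
      sint = ((f[q] + (double)q * q * s2) - (f[p] + (double)p * p * s2)) /
             (2.0 * s2 * (q - p));
      if (sint <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = sint;
    z[k + 1] = INF;
  }
  if (f[v[0]] == INF) {  // entire line empty
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;  // intersections are in index units
    const double dq = ((double)q - v[k]) * s;
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cppEDTFromSeeds(LogicalVector seed, IntegerVector dims,
                              NumericVector spacing) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nz * ny * nx;
  NumericVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = seed[i] ? 0.0 : INF;

  std::vector<double> f(std::max(nz, std::max(ny, nx)));
  std::vector<double> d(f.size());

  // along z (stride 1)
  for (R_xlen_t c = 0; c < (R_xlen_t)ny * nx; ++c) {
    double *col = &out[0] + c * nz;
    for (int i = 0; i < nz; ++i) f[i] = col[i];
    dt1d(f.data(), d.data(), nz, spacing[0]);
    for (int i = 0; i < nz; ++i) col[i] = d[i];
  }
  // along y (stride nz)
  for (int ix = 0; ix < nx; ++ix) {
    for (int iz = 0; iz < nz; ++iz) {
      double *base = &out[0] + iz + (R_xlen_t)nz * ny * ix;
      for (int i = 0; i < ny; ++i) f[i] = base[(R_xlen_t)nz * i];
      dt1d(f.data(), d.data(), ny, spacing[1]);
      for (int i = 0; i < ny; ++i) base[(R_xlen_t)nz * i] = d[i];
    }
  }
  // along x (stride nz*ny)
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (R_xlen_t c = 0; c < sx; ++c) {
    double *base = &out[0] + c;
    for (int i = 0; i < nx; ++i) f[i] = base[sx * i];
    dt1d(f.data(), d.data(), nx, spacing[2]);
    for (int i = 0; i < nx; ++i) base[sx * i] = d[i];
  }
  for (R_xlen_t i = 0; i < nvox; ++i)
    out[i] = (out[i] == INF) ? R_PosInf : std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
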