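#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Trilinear or nearest-neighbour sampling of a 3-D array at continuous
// 0-based voxel indices. Points outside the grid sample to NA.
// [[Rcpp::export]]
NumericVector cpp_sample3d(NumericVector img, IntegerVector dim,
                           NumericMatrix idx, bool nearest) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *im = img.begin();
  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (nearest) {
      const long i = std::lround(x), j = std::lround(y), k = std::lround(z);
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) {
        out[p] = NA_REAL;
      } else {
        out[p] = im[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      }
    } else {
      if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
            x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0)) {
        out[p] = NA_REAL;
        continue;
      }
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
      if (i0 == nx - 1) --i0;
      if (j0 == ny - 1) --j0;
      if (k0 == nz - 1) --k0;
      if (nx == 1) i0 = 0;
      if (ny == 1) j0 = 0;
      if (nz == 1) k0 = 0;
      const double fx = x - i0, fy = y - j0, fz = z - k0;
      const int i1 = (nx == 1) ? i0 : i0 + 1;
      const int j1 = (ny == 1) ? j0 : j0 + 1;
      const int k1 = (nz == 1) ? k0 : k0 + 1;
      #define AT(i, j, k) im[(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
      const double c00 = AT(i0, j0, k0) * (1 - fx) + AT(i1, j0, k0) * fx;
      const double c10 = AT(i0, j1, k0) * (1 - fx) + AT(i1, j1, k0) * fx;
      const double c01 = AT(i0, j0, k1) * (1 - fx) + AT(i1, j0, k1) * fx;
      const double c11 = AT(i0, j1, k1) * (1 - fx) + AT(i1, j1, k1) * fx;
      #undef AT
      const double c0 = c00 * (1 - fy) + c10 * fy;
      const double c1 = c01 * (1 - fy) + c11 * fy;
      out[p] = c0 * (1 - fz) + c1 * fz;
    }
  }
  return out;
}

// Adjoint of trilinear interpolation: accumulate `vals` at continuous
// 0-based indices `idx` into a grid of dimension `dim`. Points outside the
// grid are dropped. Returns the accumulation grid as a vector (column-major).
// [[Rcpp::export]]
NumericVector cpp_splat3d(NumericVector vals, IntegerVector dim,
                          NumericMatrix idx) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector grid((R_xlen_t)nx * ny * nz);
  double *g = grid.begin();
  const R_xlen_t n = idx.nrow();
  for (R_xlen_t p = 0; p < n; ++p) {
    const double v = vals[p];
    if (!R_finite(v)) continue;
    const double x = idx(p, 0), y = idx(p, 1), z = idx(p, 2);
    if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
          x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0)) continue;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == nx - 1 && nx > 1) --i0;
    if (j0 == ny - 1 && ny > 1) --j0;
    if (k0 == nz - 1 && nz > 1) --k0;
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const int i1 = (nx == 1) ? i0 : i0 + 1;
    const int j1 = (ny == 1) ? j0 : j0 + 1;
    const int k1 = (nz == 1) ? k0 : k0 + 1;
    const double wx[2] = {1 - fx, fx}, wy[2] = {1 - fy, fy}, wz[2] = {1 - fz, fz};
    const int ii[2] = {i0, i1}, jj[2] = {j0, j1}, kk[2] = {k0, k1};
    for (int c = 0; c < 2; ++c)
      for (int b = 0; b < 2; ++b)
        for (int a = 0; a < 2; ++a) {
          const double w = wx[a] * wy[b] * wz[c];
          if (w == 0.0) continue;
          g[ii[a] + (R_xlen_t)nx * (jj[b] + (R_xlen_t)ny * kk[c])] += w * v;
        }
  }
  return grid;
}

// Joint intensity histogram with bilinear (partial-volume) spreading of each
// sample over the two nearest bins per axis; `soft = false` gives hard
// binning. Bin centres sit at (i + 0.5) * width. Returns a bins x bins matrix.
// [[Rcpp::export]]
NumericMatrix cpp_joint_hist(NumericVector a, NumericVector b, int bins,
                             double amin, double awidth, double bmin,
                             double bwidth, bool soft) {
  NumericMatrix h(bins, bins);
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    double xa = (a[i] - amin) / awidth;
    double xb = (b[i] - bmin) / bwidth;
    if (!soft) {
      int ia = std::min((int)xa, bins - 1), ib = std::min((int)xb, bins - 1);
      h(ia, ib) += 1.0;
      continue;
    }
    xa -= 0.5; xb -= 0.5;
    int ia0 = (int)std::floor(xa), ib0 = (int)std::floor(xb);
    const double fa = xa - ia0, fb = xb - ib0;
    const double wa[2] = {1 - fa, fa}, wb[2] = {1 - fb, fb};
    for (int db = 0; db < 2; ++db)
      for (int da = 0; da < 2; ++da) {
        int ia = ia0 + da, ib = ib0 + db;
        if (ia < 0) ia = 0; if (ia >= bins) ia = bins - 1;
        if (ib < 0) ib = 0; if (ib >= bins) ib = bins - 1;
        h(ia, ib) += wa[da] * wb[db];
      }
  }
  return h;
}

// One-dimensional squared distance transform (Felzenszwalb & Huttenlocher)
// with physical sample positions i * s.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 int n, double s) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;  // no parabola yet; skip infinite sources entirely
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    const double xq = q * s;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double sden = 2.0 * (xq - v[k] * s);
    double sk = ((f[q] + xq * xq) - (f[v[k]] + (v[k] * s) * (v[k] * s))) / sden;
    while (k >= 0 && sk <= z[k]) {
      --k;
      if (k < 0) break;
      sden = 2.0 * (xq - v[k] * s);
      sk = ((f[q] + xq * xq) - (f[v[k]] + (v[k] * s) * (v[k] * s))) / sden;
    }
    ++k;
    v[k] = q;
    z[k] = (k == 0) ? -INF : sk;
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double dx = xq - v[k] * s;
    d[q] = dx * dx + f[v[k]];
  }
}

// Anisotropic squared Euclidean distance transform: for every voxel, the
// squared physical distance (mm^2) to the nearest TRUE voxel of `mask`.
// [[Rcpp::export]]
NumericVector cpp_sedt(LogicalVector mask, IntegerVector dim,
                       NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j)
        f[j] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, ny, spacing[1]);
      for (int j = 0; j < ny; ++j)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k)
        f[k] = out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)];
      dt1d(f, d, nz, spacing[2]);
      for (int k = 0; k < nz; ++k)
        out[i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = d[k];
    }
  return out;
}

// Block-mean downsampling by integer factor along each axis (truncating any
// remainder), used to build the multi-resolution pyramid.
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector img, IntegerVector dim, int f) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int mx = nx / f, my = ny / f, mz = nz / f;
  NumericVector out((R_xlen_t)mx * my * mz);
  const double inv = 1.0 / ((double)f * f * f);
  for (int k = 0; k < mz; ++k)
    for (int j = 0; j < my; ++j)
      for (int i = 0; i < mx; ++i) {
        double s = 0.0;
        for (int c = 0; c < f; ++c)
          for (int b = 0; b < f; ++b)
            for (int a = 0; a < f; ++a)
              s += img[(i * f + a) +
                       (R_xlen_t)nx * ((j * f + b) + (R_xlen_t)ny * (k * f + c))];
        out[i + (R_xlen_t)mx * (j + (R_xlen_t)my * k)] = s * inv;
      }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}
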