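#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Large finite sentinel standing for "no feature yet"; BIG + n^2 stays exact
// in double precision for any realistic lattice.
static const double BIG = 1e15;

// One-dimensional squared distance transform (lower envelope of parabolas,
// Felzenszwalb & Huttenlocher).
static void edt1d(const std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (voxel units, voxel centers) from every lattice
// site to the nearest TRUE voxel of `feature`. Values >= 1e14 mean the
// feature set is empty.
// [[Rcpp::export]]
NumericVector edt3d_sq_cpp(LogicalVector feature, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((R_xlen_t)nx * ny * nz != feature.size())
    stop("feature length does not match dims");
  NumericVector D(feature.size());
  for (R_xlen_t i = 0; i < feature.size(); ++i)
    D[i] = (feature[i] == TRUE) ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int zz = 0; zz < nz; ++zz)          // axis 1 (fastest varying)
    for (int yy = 0; yy < ny; ++yy) {
      R_xlen_t base = (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
      for (int x = 0; x < nx; ++x) f[x] = D[base + x];
      edt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; ++x) D[base + x] = d[x];
    }
  for (int zz = 0; zz < nz; ++zz)          // axis 2
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)nx * y];
      edt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)nx * y] = d[y];
    }
  for (int yy = 0; yy < ny; ++yy)          // axis 3
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = x + (R_xlen_t)nx * yy;
      for (int zz = 0; zz < nz; ++zz) f[zz] = D[base + (R_xlen_t)nx * ny * zz];
      edt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; ++zz) D[base + (R_xlen_t)nx * ny * zz] = d[zz];
    }
  D.attr("dim") = dims;
  return D;
}
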