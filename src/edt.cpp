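#include <Rcpp.h>
using namespace Rcpp;

// Separable squared Euclidean distance transform (lower envelope of
// parabolas, Felzenszwalb & Huttenlocher). Each pass operates along one
// axis with physical step h, so anisotropic voxel spacing is exact.

static const double BIG = 1e20; // finite stand-in for "no site on this line"

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h, std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double h2 = h * h;
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      int p = v[k];
      // physical-coordinate intersection of the parabolas rooted at p and q
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h * (q - p));
      if (k > 0 && s <= z[k]) {
        k--;
      } else {
        break;
      }
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < h * q) k++;
    double dq = h * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Distance (mm) from each voxel centre to the nearest voxel centre with
// mask == TRUE. per_slice = TRUE restricts the transform to each z-slice.
// Voxels on slices (or volumes) with no TRUE voxel get sqrt(BIG); callers
// cap or mark those.
// [[Rcpp::export(name = ".edt_mm")]]
NumericVector edt_mm(LogicalVector mask, IntegerVector dims,
                     NumericVector spacing, bool per_slice) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox);

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // init: 0 at sites, BIG elsewhere
  for (R_xlen_t i = 0; i < nvox; i++) out[i] = mask[i] ? 0.0 : BIG;

  // pass along x for every (y, z) line
  for (int kz = 0; kz < nz; kz++) {
    for (int jy = 0; jy < ny; jy++) {
      R_xlen_t base = (R_xlen_t)nx * (jy + (R_xlen_t)ny * kz);
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, nx, dx, v, z);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  }
  // pass along y
  for (int kz = 0; kz < nz; kz++) {
    for (int ix = 0; ix < nx; ix++) {
      R_xlen_t base = ix + (R_xlen_t)nx * ny * kz;
      for (int j = 0; j < ny; j++) f[j] = out[base + (R_xlen_t)nx * j];
      dt1d(f, d, ny, dy, v, z);
      for (int j = 0; j < ny; j++) out[base + (R_xlen_t)nx * j] = d[j];
    }
  }
  // pass along z (3D mode only)
  if (!per_slice && nz > 1) {
    for (int jy = 0; jy < ny; jy++) {
      for (int ix = 0; ix < nx; ix++) {
        R_xlen_t base = ix + (R_xlen_t)nx * jy;
        R_xlen_t stride = (R_xlen_t)nx * ny;
        for (int k = 0; k < nz; k++) f[k] = out[base + stride * k];
        dt1d(f, d, nz, dz, v, z);
        for (int k = 0; k < nz; k++) out[base + stride * k] = d[k];
      }
    }
  }

  for (R_xlen_t i = 0; i < nvox; i++) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
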