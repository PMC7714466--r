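#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Squared 1D distance transform (Felzenszwalb & Huttenlocher) with physical
// sample spacing s. f holds squared distances; result overwrites d.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double s) {
  std::vector<int> v(n);
  std::vector<double> zz(n + 1);
  int k = 0;
  v[0] = 0;
  zz[0] = -1e300; zz[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double sden, sloc;
    while (true) {
      double vs = v[k] * s;
      sden = 2 * qs - 2 * vs;
      sloc = (f[q] + qs * qs - (f[v[k]] + vs * vs)) / sden;
      if (sloc <= zz[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    zz[k] = sloc;
    zz[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (zz[k + 1] < qs) k++;
    double vs = v[k] * s;
    d[q] = (qs - vs) * (qs - vs) + f[v[k]];
  }
}

// Anisotropic Euclidean distance transform: for every foreground voxel the
// physical distance to the nearest background voxel centre. Voxels outside
// the array count as background at one spacing step beyond the border.
// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  // pad with a virtual background layer by working on an enlarged grid
  int px = nx + 2, py = ny + 2, pz = nz + 2;
  size_t N = (size_t)px * py * pz;
  std::vector<double> d(N, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        if (mask[x + nx * (y + (size_t)ny * z)])
          d[(x + 1) + (size_t)px * ((y + 1) + (size_t)py * (z + 1))] = 1e300;

  std::vector<double> f, o;
  // along x
  f.resize(px); o.resize(px);
  for (int z = 0; z < pz; ++z)
    for (int y = 0; y < py; ++y) {
      size_t base = (size_t)px * (y + (size_t)py * z);
      for (int x = 0; x < px; ++x) f[x] = d[base + x];
      dt1d(f, o, px, spacing[0]);
      for (int x = 0; x < px; ++x) d[base + x] = o[x];
    }
  // along y
  f.resize(py); o.resize(py);
  for (int z = 0; z < pz; ++z)
    for (int x = 0; x < px; ++x) {
      for (int y = 0; y < py; ++y) f[y] = d[x + (size_t)px * (y + (size_t)py * z)];
      dt1d(f, o, py, spacing[1]);
      for (int y = 0; y < py; ++y) d[x + (size_t)px * (y + (size_t)py * z)] = o[y];
    }
  // along z
  f.resize(pz); o.resize(pz);
  for (int y = 0; y < py; ++y)
    for (int x = 0; x < px; ++x) {
      for (int z = 0; z < pz; ++z) f[z] = d[x + (size_t)px * (y + (size_t)py * z)];
      dt1d(f, o, pz, spacing[2]);
      for (int z = 0; z < pz; ++z) d[x + (size_t)px * (y + (size_t)py * z)] = o[z];
    }

  NumericVector out(mask.size());
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x)
        out[x + nx * (y + (size_t)ny * z)] =
          std::sqrt(d[(x + 1) + (size_t)px * ((y + 1) + (size_t)py * (z + 1))]);
  out.attr("dim") = dim;
  return out;
}
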