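#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int IDX(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Value of f at (x,y,z), zero outside the array (crops are background-padded
// by construction, so out-of-bounds reads as background).
static inline double FVAL(const double* f, int x, int y, int z,
                          int nx, int ny, int nz) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0.0;
  return f[IDX(x, y, z, nx, ny)];
}
static inline bool MVAL(const int* m, int x, int y, int z,
                        int nx, int ny, int nz) {
  if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
  return m[IDX(x, y, z, nx, ny)] != 0;
}

// Exposed voxel faces (6-connectivity), counted per axis.
// [[Rcpp::export]]
NumericVector cpp_exposed_faces(IntegerVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* m = INTEGER(mask);
  double cx = 0, cy = 0, cz = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!m[IDX(x, y, z, nx, ny)]) continue;
        if (!MVAL(m, x - 1, y, z, nx, ny, nz)) cx++;
        if (!MVAL(m, x + 1, y, z, nx, ny, nz)) cx++;
        if (!MVAL(m, x, y - 1, z, nx, ny, nz)) cy++;
        if (!MVAL(m, x, y + 1, z, nx, ny, nz)) cy++;
        if (!MVAL(m, x, y, z - 1, nx, ny, nz)) cz++;
        if (!MVAL(m, x, y, z + 1, nx, ny, nz)) cz++;
      }
  return NumericVector::create(cx, cy, cz);
}

// Outward unit normals at boundary voxels, from central finite differences of
// the raw image f scaled by the physical voxel spacing, optionally smoothed
// by iterated averaging over 26-adjacent boundary voxels. Boundary voxels are
// foreground voxels with at least one of their 6 face neighbours in the
// background. Returns the boundary voxel linear indices (1-based), the unit
// normals, and the surfel (projected-face) surface area.
// [[Rcpp::export]]
List cpp_surfel(IntegerVector mask, NumericVector f, IntegerVector dim,
                NumericVector spacing, int iterations) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* m = INTEGER(mask);
  const double* fp = REAL(f);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];

  std::vector<int> bidx;
  int n = mask.size();
  std::vector<int> brank(n, -1);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = IDX(x, y, z, nx, ny);
        if (!m[i]) continue;
        if (!MVAL(m, x - 1, y, z, nx, ny, nz) || !MVAL(m, x + 1, y, z, nx, ny, nz) ||
            !MVAL(m, x, y - 1, z, nx, ny, nz) || !MVAL(m, x, y + 1, z, nx, ny, nz) ||
            !MVAL(m, x, y, z - 1, nx, ny, nz) || !MVAL(m, x, y, z + 1, nx, ny, nz)) {
          brank[i] = bidx.size();
          bidx.push_back(i);
        }
      }
  int nb = bidx.size();
  std::vector<double> nxv(nb), nyv(nb), nzv(nb);

  for (int k = 0; k < nb; ++k) {
    int i = bidx[k];
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    // outward normal = -gradient (f is high inside the object)
    nxv[k] = -(FVAL(fp, x + 1, y, z, nx, ny, nz) - FVAL(fp, x - 1, y, z, nx, ny, nz)) / (2 * sx);
    nyv[k] = -(FVAL(fp, x, y + 1, z, nx, ny, nz) - FVAL(fp, x, y - 1, z, nx, ny, nz)) / (2 * sy);
    nzv[k] = -(FVAL(fp, x, y, z + 1, nx, ny, nz) - FVAL(fp, x, y, z - 1, nx, ny, nz)) / (2 * sz);
  }

  // on-surface smoothing: average over 26-adjacent boundary voxels
  for (int it = 0; it < iterations; ++it) {
    std::vector<double> ax(nb), ay(nb), az(nb);
    for (int k = 0; k < nb; ++k) {
      int i = bidx[k];
      int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
      double sxv = nxv[k], syv = nyv[k], szv = nzv[k];
      int cnt = 1;
      for (int a = -1; a <= 1; ++a)
        for (int b = -1; b <= 1; ++b)
          for (int c = -1; c <= 1; ++c) {
            if (!a && !b && !c) continue;
            int qx = x + a, qy = y + b, qz = z + c;
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
              continue;
            int r = brank[IDX(qx, qy, qz, nx, ny)];
            if (r >= 0) { sxv += nxv[r]; syv += nyv[r]; szv += nzv[r]; cnt++; }
          }
      ax[k] = sxv / cnt; ay[k] = syv / cnt; az[k] = szv / cnt;
    }
    nxv.swap(ax); nyv.swap(ay); nzv.swap(az);
  }

  // normalize; fall back to the mean exposed-face direction on zero gradient
  double area = 0.0;
  const double fax = sy * sz, fay = sx * sz, faz = sx * sy;
  NumericMatrix normals(nb, 3);
  IntegerVector out_idx(nb);
  for (int k = 0; k < nb; ++k) {
    int i = bidx[k];
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    int ex_lo = !MVAL(m, x - 1, y, z, nx, ny, nz), ex_hi = !MVAL(m, x + 1, y, z, nx, ny, nz);
    int ey_lo = !MVAL(m, x, y - 1, z, nx, ny, nz), ey_hi = !MVAL(m, x, y + 1, z, nx, ny, nz);
    int ez_lo = !MVAL(m, x, y, z - 1, nx, ny, nz), ez_hi = !MVAL(m, x, y, z + 1, nx, ny, nz);
    double vx = nxv[k], vy = nyv[k], vz = nzv[k];
    double len = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (len == 0.0) {
      vx = ex_hi - ex_lo; vy = ey_hi - ey_lo; vz = ez_hi - ez_lo;
      len = std::sqrt(vx * vx + vy * vy + vz * vz);
    }
    if (len > 0) { vx /= len; vy /= len; vz /= len; }
    normals(k, 0) = vx; normals(k, 1) = vy; normals(k, 2) = vz;
    out_idx[k] = i + 1;
    if (len == 0.0) {
      // fully degenerate (e.g. isolated voxel): each exposed face counts in
      // full, reproducing the exposed-face area locally
      area += fax * (ex_lo + ex_hi) + fay * (ey_lo + ey_hi) +
        faz * (ez_lo + ez_hi);
      continue;
    }
    // per-surfel contribution: face area x (normal . outward face direction),
    // clamped at zero (guards inward-flipped normals on noisy data)
    if (ex_lo) area += fax * std::max(0.0, -vx);
    if (ex_hi) area += fax * std::max(0.0, vx);
    if (ey_lo) area += fay * std::max(0.0, -vy);
    if (ey_hi) area += fay * std::max(0.0, vy);
    if (ez_lo) area += faz * std::max(0.0, -vz);
    if (ez_hi) area += faz * std::max(0.0, vz);
  }
  return List::create(_["area"] = area, _["index"] = out_idx,
                      _["normals"] = normals);
}
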