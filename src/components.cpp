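#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Linear index helpers for column-major 3D arrays (dim = nx, ny, nz).
static inline int IDX(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// 26-neighbourhood offsets, generated once.
static void neighbours(int conn, std::vector<int>& dx, std::vector<int>& dy,
                       std::vector<int>& dz) {
  dx.clear(); dy.clear(); dz.clear();
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && m != 1) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// Label connected foreground components of a 3D binary array.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerVector lab(mask.size(), 0);
  std::vector<int> dx, dy, dz;
  neighbours(connectivity, dx, dy, dz);
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = IDX(x, y, z, nx, ny);
        if (!mask[i] || lab[i]) continue;
        lab[i] = ++next;
        stack.clear();
        stack.push_back(i);
        while (!stack.empty()) {
          int j = stack.back(); stack.pop_back();
          int jx = j % nx, jy = (j / nx) % ny, jz = j / (nx * ny);
          for (size_t k = 0; k < dx.size(); ++k) {
            int qx = jx + dx[k], qy = jy + dy[k], qz = jz + dz[k];
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
              continue;
            int q = IDX(qx, qy, qz, nx, ny);
            if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

// Fill interior cavities: background voxels not 6-connected to the array
// border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = mask.size();
  std::vector<char> outside(n, 0);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool border = (x == 0 || y == 0 || z == 0 ||
                       x == nx - 1 || y == ny - 1 || z == nz - 1);
        if (!border) continue;
        int i = IDX(x, y, z, nx, ny);
        if (!mask[i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
  const int ddx[6] = {1,-1,0,0,0,0}, ddy[6] = {0,0,1,-1,0,0}, ddz[6] = {0,0,0,0,1,-1};
  while (!stack.empty()) {
    int j = stack.back(); stack.pop_back();
    int jx = j % nx, jy = (j / nx) % ny, jz = j / (nx * ny);
    for (int k = 0; k < 6; ++k) {
      int qx = jx + ddx[k], qy = jy + ddy[k], qz = jz + ddz[k];
      if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz) continue;
      int q = IDX(qx, qy, qz, nx, ny);
      if (!mask[q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  out.attr("dim") = dim;
  return out;
}

// Slice-wise (XY) 2D hole fill: per slice, background pixels not 4-connected
// to the slice border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes_slices(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out = clone(mask);
  std::vector<char> outside((size_t)nx * ny);
  std::vector<int> stack;
  for (int z = 0; z < nz; ++z) {
    std::fill(outside.begin(), outside.end(), 0);
    stack.clear();
    int off = nx * ny * z;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && y != 0 && x != nx - 1 && y != ny - 1) continue;
        int i = x + nx * y;
        if (!mask[off + i] && !outside[i]) { outside[i] = 1; stack.push_back(i); }
      }
    const int ddx[4] = {1,-1,0,0}, ddy[4] = {0,0,1,-1};
    while (!stack.empty()) {
      int j = stack.back(); stack.pop_back();
      int jx = j % nx, jy = j / nx;
      for (int k = 0; k < 4; ++k) {
        int qx = jx + ddx[k], qy = jy + ddy[k];
        if (qx < 0 || qy < 0 || qx >= nx || qy >= ny) continue;
        int q = qx + nx * qy;
        if (!mask[off + q] && !outside[q]) { outside[q] = 1; stack.push_back(q); }
      }
    }
    for (int i = 0; i < nx * ny; ++i)
      if (!outside[i]) out[off + i] = true;
  }
  out.attr("dim") = dim;
  return out;
}

// Component sizes and tight bounding boxes from a label array.
// Returns a matrix with one row per label: n_voxels, x0, x1, y0, y1, z0, z1
// (0-based inclusive bounds).
// [[Rcpp::export]]
IntegerMatrix cpp_component_stats(IntegerVector lab, IntegerVector dim, int nlab) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  IntegerMatrix out(nlab, 7);
  for (int l = 0; l < nlab; ++l) {
    out(l, 1) = nx; out(l, 3) = ny; out(l, 5) = nz;
    out(l, 2) = -1; out(l, 4) = -1; out(l, 6) = -1;
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int l = lab[IDX(x, y, z, nx, ny)];
        if (l <= 0) continue;
        int r = l - 1;
        out(r, 0)++;
        if (x < out(r, 1)) out(r, 1) = x;
        if (x > out(r, 2)) out(r, 2) = x;
        if (y < out(r, 3)) out(r, 3) = y;
        if (y > out(r, 4)) out(r, 4) = y;
        if (z < out(r, 5)) out(r, 5) = z;
        if (z > out(r, 6)) out(r, 6) = z;
      }
  return out;
}
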