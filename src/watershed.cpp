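#include <Rcpp.h>
#include <queue>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int IDX(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Regional maxima (26-connected plateaus with no higher neighbour) of the
// intensity restricted to a region mask. Returns integer labels, 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector img, LogicalVector region,
                                  IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = img.size();
  IntegerVector lab(n, 0);
  std::vector<char> visited(n, 0);
  std::vector<int> plateau, stack;
  int next = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = IDX(x, y, z, nx, ny);
        if (!region[i] || visited[i]) continue;
        double v = img[i];
        // flood the equal-value plateau, checking for higher neighbours
        bool is_max = true;
        plateau.clear(); stack.clear();
        stack.push_back(i); visited[i] = 1;
        while (!stack.empty()) {
          int j = stack.back(); stack.pop_back();
          plateau.push_back(j);
          int jx = j % nx, jy = (j / nx) % ny, jz = j / (nx * ny);
          for (int a = -1; a <= 1; ++a)
            for (int b = -1; b <= 1; ++b)
              for (int c = -1; c <= 1; ++c) {
                if (!a && !b && !c) continue;
                int qx = jx + a, qy = jy + b, qz = jz + c;
                if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
                  continue;
                int q = IDX(qx, qy, qz, nx, ny);
                if (!region[q]) continue;
                if (img[q] > v) { is_max = false; continue; }
                if (img[q] == v && !visited[q]) {
                  visited[q] = 1; stack.push_back(q);
                }
              }
        }
        if (is_max) {
          ++next;
          for (size_t k = 0; k < plateau.size(); ++k) lab[plateau[k]] = next;
        }
      }
  lab.attr("dim") = dim;
  return lab;
}

struct QItem {
  double v; long order; int idx; int lab;
  bool operator<(const QItem& o) const {
    if (v != o.v) return v < o.v;          // max-heap on intensity
    return order > o.order;                 // FIFO on ties
  }
};

// Seeded watershed by priority flooding on the intensity (brightest first),
// restricted to a region mask. Every seed voxel keeps its label. Returns the
// label array and a saddle table (label a, label b, highest meeting
// intensity) used for h-criterion basin merging.
// [[Rcpp::export]]
List cpp_watershed(NumericVector img, LogicalVector region, IntegerVector seeds,
                   IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = img.size();
  IntegerVector lab(n, 0);
  std::priority_queue<QItem> pq;
  long order = 0;
  for (int i = 0; i < n; ++i) {
    if (seeds[i] > 0 && region[i]) {
      lab[i] = seeds[i];
    }
  }
  for (int i = 0; i < n; ++i)
    if (lab[i] > 0) pq.push({img[i], order++, i, lab[i]});

  std::map<std::pair<int, int>, double> saddle;
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int jx = it.idx % nx, jy = (it.idx / nx) % ny, jz = it.idx / (nx * ny);
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (!a && !b && !c) continue;
          int qx = jx + a, qy = jy + b, qz = jz + c;
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
            continue;
          int q = IDX(qx, qy, qz, nx, ny);
          if (!region[q]) continue;
          if (lab[q] == 0) {
            lab[q] = it.lab;
            pq.push({img[q], order++, q, it.lab});
          } else if (lab[q] != it.lab) {
            int l1 = std::min(lab[q], it.lab), l2 = std::max(lab[q], it.lab);
            double meet = std::min(img[q], it.v);
            auto key = std::make_pair(l1, l2);
            auto f = saddle.find(key);
            if (f == saddle.end() || meet > f->second) saddle[key] = meet;
          }
        }
  }
  int ns = saddle.size();
  IntegerVector sa(ns), sb(ns);
  NumericVector sv(ns);
  int k = 0;
  for (auto& kv : saddle) {
    sa[k] = kv.first.first; sb[k] = kv.first.second; sv[k] = kv.second; ++k;
  }
  lab.attr("dim") = dim;
  return List::create(_["labels"] = lab, _["saddle_a"] = sa,
                      _["saddle_b"] = sb, _["saddle_value"] = sv);
}

// Separable Gaussian blur with per-axis sigma in voxel units; reflecting
// boundaries. sigma 0 skips an axis.
// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector img, IntegerVector dim,
                             NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> cur(img.begin(), img.end()), nxt(img.size());
  int dims[3] = {nx, ny, nz};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> kern(2 * r + 1);
    double sum = 0;
    for (int i = -r; i <= r; ++i) {
      kern[i + r] = std::exp(-0.5 * i * i / (s * s));
      sum += kern[i + r];
    }
    for (auto& v : kern) v /= sum;
    int nlen = dims[ax];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int pos[3] = {x, y, z};
          double acc = 0;
          for (int i = -r; i <= r; ++i) {
            int p = pos[ax] + i;
            if (p < 0) p = -p - 1;
            if (p >= nlen) p = 2 * nlen - p - 1;
            int c[3] = {pos[0], pos[1], pos[2]};
            c[ax] = p;
            acc += kern[i + r] * cur[IDX(c[0], c[1], c[2], nx, ny)];
          }
          nxt[IDX(x, y, z, nx, ny)] = acc;
        }
    cur.swap(nxt);
  }
  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = dim;
  return out;
}
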