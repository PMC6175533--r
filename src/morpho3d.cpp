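#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 3D morphology primitives shared by the segmentation and features modules.
// Arrays are indexed [row (y), col (x), slice (z)], column-major as in R.

static inline R_xlen_t idx3(int y, int x, int z, int ny, int nx) {
  return (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
}

// ---- Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
//
// One-dimensional squared-distance transform on a grid with physical step
// `h`: f holds squared distances, positions are i*h.
static void dt1d(std::vector<double> &f, double h) {
  const int n = (int)f.size();
  if (n == 0) return;
  std::vector<int> v(n);
  std::vector<double> zb(n + 1), d(n);
  int k = 0;
  v[0] = 0;
  zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s > zb[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (zb[k + 1] < xq) ++k;
    double dx = xq - v[k] * h;
    d[q] = dx * dx + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Euclidean distance (physical units) from each foreground voxel to the
// nearest background voxel. spacing = (y, x, z) step sizes.
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(LogicalVector fg, IntegerVector dims,
                        NumericVector spacing) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  const double hy = spacing[0], hx = spacing[1], hz = spacing[2];
  // large finite sentinel: infinity would make the envelope intersections NaN
  const double INF = 1e15;
  NumericVector out(fg.size());
  for (R_xlen_t i = 0; i < fg.size(); ++i) out[i] = fg[i] ? INF : 0.0;

  std::vector<double> buf;
  // y direction
  buf.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) buf[y] = out[idx3(y, x, z, ny, nx)];
      dt1d(buf, hy);
      for (int y = 0; y < ny; ++y) out[idx3(y, x, z, ny, nx)] = buf[y];
    }
  // x direction
  buf.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) buf[x] = out[idx3(y, x, z, ny, nx)];
      dt1d(buf, hx);
      for (int x = 0; x < nx; ++x) out[idx3(y, x, z, ny, nx)] = buf[x];
    }
  // z direction
  buf.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) buf[z] = out[idx3(y, x, z, ny, nx)];
      dt1d(buf, hz);
      for (int z = 0; z < nz; ++z) out[idx3(y, x, z, ny, nx)] = buf[z];
    }
  for (R_xlen_t i = 0; i < out.size(); ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}

// Neighbour offsets for 6/18/26-connectivity in 3D (8-connectivity in 2D is
// the nz == 1 restriction of 26).
static void neighbours(int conn, std::vector<int> &dy, std::vector<int> &dx,
                       std::vector<int> &dz) {
  for (int z = -1; z <= 1; ++z)
    for (int x = -1; x <= 1; ++x)
      for (int y = -1; y <= 1; ++y) {
        int m = std::abs(y) + std::abs(x) + std::abs(z);
        if (m == 0) continue;
        if (conn == 6 && m > 1) continue;
        if (conn == 18 && m > 2) continue;
        dy.push_back(y); dx.push_back(x); dz.push_back(z);
      }
}

// Connected-component labelling of a binary mask; labels are consecutive
// positive integers in scan order of the first voxel encountered.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dims, int conn) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  std::vector<int> dy, dx, dz;
  neighbours(conn, dy, dx, dz);
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = idx3(y, x, z, ny, nx);
        if (!mask[i] || lab[i]) continue;
        ++next;
        lab[i] = next;
        stack.push_back(i);
        while (!stack.empty()) {
          R_xlen_t c = stack.back(); stack.pop_back();
          int cz = (int)(c / ((R_xlen_t)ny * nx));
          int rem = (int)(c - (R_xlen_t)cz * ny * nx);
          int cx = rem / ny, cy = rem % ny;
          for (size_t k = 0; k < dy.size(); ++k) {
            int yy = cy + dy[k], xx = cx + dx[k], zz = cz + dz[k];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            R_xlen_t j = idx3(yy, xx, zz, ny, nx);
            if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Regional maxima of `img` restricted to `mask`, plateau-aware: a plateau is
// a maximum iff no voxel adjacent to it has a strictly larger value. Returns
// consecutive positive labels, one per maximal plateau.
// [[Rcpp::export(name = ".cpp_regmax3d")]]
IntegerVector cpp_regmax3d(NumericVector img, LogicalVector mask,
                           IntegerVector dims, int conn) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  std::vector<int> dy, dx, dz;
  neighbours(conn, dy, dx, dz);
  IntegerVector lab(img.size()); // 0 unvisited, -1 visited non-max, >0 seed id
  std::vector<char> visited(img.size(), 0);
  int next = 0;
  std::vector<R_xlen_t> comp, stack;
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x)
      for (int y = 0; y < ny; ++y) {
        R_xlen_t i = idx3(y, x, z, ny, nx);
        if (!mask[i] || visited[i]) continue;
        // flood the plateau of equal value containing i
        double v = img[i];
        bool is_max = true;
        comp.clear();
        stack.clear();
        stack.push_back(i);
        visited[i] = 1;
        while (!stack.empty()) {
          R_xlen_t c = stack.back(); stack.pop_back();
          comp.push_back(c);
          int cz = (int)(c / ((R_xlen_t)ny * nx));
          int rem = (int)(c - (R_xlen_t)cz * ny * nx);
          int cx = rem / ny, cy = rem % ny;
          for (size_t k = 0; k < dy.size(); ++k) {
            int yy = cy + dy[k], xx = cx + dx[k], zz = cz + dz[k];
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
              continue;
            R_xlen_t j = idx3(yy, xx, zz, ny, nx);
            if (!mask[j]) continue;
            if (img[j] > v) { is_max = false; continue; }
            if (img[j] == v && !visited[j]) { visited[j] = 1; stack.push_back(j); }
          }
        }
        if (is_max) {
          ++next;
          for (size_t k = 0; k < comp.size(); ++k) lab[comp[k]] = next;
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

struct WsNode {
  double priority;   // flood order: higher priority popped first
  long long order;   // FIFO tie-break for determinism
  R_xlen_t idx;
  int label;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;
  }
};

// Seeded watershed by priority flooding: regions grow from `seeds` outward
// through `mask`, visiting high-`priority` voxels first (for splitting round
// particles, priority is the smoothed distance map). Every masked voxel
// 26/18/6-connected to a seed receives the label of the region that reaches
// it first; ties are resolved by deterministic FIFO insertion order.
// [[Rcpp::export(name = ".cpp_watershed3d")]]
IntegerVector cpp_watershed3d(NumericVector priority, IntegerVector seeds,
                              LogicalVector mask, IntegerVector dims,
                              int conn) {
  const int ny = dims[0], nx = dims[1], nz = dims[2];
  std::vector<int> dy, dx, dz;
  neighbours(conn, dy, dx, dz);
  IntegerVector lab(priority.size());
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long long order = 0;
  for (R_xlen_t i = 0; i < seeds.size(); ++i)
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(WsNode{priority[i], order++, i, seeds[i]});
    }
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    R_xlen_t c = nd.idx;
    int cz = (int)(c / ((R_xlen_t)ny * nx));
    int rem = (int)(c - (R_xlen_t)cz * ny * nx);
    int cx = rem / ny, cy = rem % ny;
    for (size_t k = 0; k < dy.size(); ++k) {
      int yy = cy + dy[k], xx = cx + dx[k], zz = cz + dz[k];
      if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = idx3(yy, xx, zz, ny, nx);
      if (!mask[j] || lab[j]) continue;
      lab[j] = lab[c];
      pq.push(WsNode{priority[j], order++, j, lab[j]});
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
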