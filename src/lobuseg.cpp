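#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Linear index convention: R column-major, idx = i + nx*(j + ny*k), 0-based.

static inline void neighbour_offsets(int connectivity, std::vector<int> &dx,
                                     std::vector<int> &dy, std::vector<int> &dz) {
  // Fixed enumeration order; the 6-neighbour subset is x-1,x+1,y-1,y+1,z-1,z+1.
  if (connectivity == 6) {
    int ox[] = {-1, 1, 0, 0, 0, 0};
    int oy[] = {0, 0, -1, 1, 0, 0};
    int oz[] = {0, 0, 0, 0, -1, 1};
    for (int t = 0; t < 6; ++t) { dx.push_back(ox[t]); dy.push_back(oy[t]); dz.push_back(oz[t]); }
    return;
  }
  for (int c = -1; c <= 1; ++c)
    for (int b = -1; b <= 1; ++b)
      for (int a = -1; a <= 1; ++a) {
        if (a == 0 && b == 0 && c == 0) continue;
        int man = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 18 && man > 2) continue;
        dx.push_back(a); dy.push_back(b); dz.push_back(c);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask size does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  std::vector<int> dx, dy, dz;
  neighbour_offsets(connectivity, dx, dy, dz);
  const int nb = (int)dx.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((R_xlen_t)nx * ny));
      for (int t = 0; t < nb; ++t) {
        int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[w] && lab[w] == 0) {
          lab[w] = next;
          stack.push_back(w);
        }
      }
    }
  }
  return lab;
}

// 1D squared-distance transform (lower envelope of parabolas), grid step w.
static void dt1d(const double *f, double *d, int n, double w, std::vector<int> &v,
                 std::vector<double> &z) {
  const double INF = std::numeric_limits<double>::infinity();
  v.assign(n, 0);
  z.assign(n + 1, 0.0);
  const double w2 = w * w;
  int k = -1;  // index of rightmost parabola in the lower envelope
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;  // parabolas at +Inf never enter the envelope
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;  // z[0] = -Inf bounds the loop
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  if (k < 0) {  // no finite source on this scan line
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance from each foreground voxel to the nearest
// background voxel centre, anisotropic spacing. Background voxels -> 0.
// If there is no background voxel at all, foreground voxels -> Inf.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector fg, IntegerVector dim, NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (fg.size() != n) stop("mask size does not match dim");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector D(n);
  for (R_xlen_t s = 0; s < n; ++s) D[s] = fg[s] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = D[base + i];
      dt1d(f.data(), d.data(), nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) D[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)nx * j];
      dt1d(f.data(), d.data(), ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)nx * j] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = D[base + stride * k];
      dt1d(f.data(), d.data(), nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) D[base + stride * k] = d[k];
    }
  return D;
}

struct WsEntry {
  double relief;
  R_xlen_t idx;
  unsigned long long counter;
  int label;
};
struct WsCompare {
  bool operator()(const WsEntry &a, const WsEntry &b) const {
    if (a.relief != b.relief) return a.relief > b.relief;
    if (a.idx != b.idx) return a.idx > b.idx;
    return a.counter > b.counter;
  }
};

// Seeded priority-flood watershed restricted to mask, 6-connectivity.
// Flooding order: ascending relief, ties by ascending linear voxel index,
// remaining ties (same voxel queued for several labels) by insertion order.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector relief, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (relief.size() != n || seeds.size() != n || mask.size() != n)
    stop("relief, seeds and mask must all match dim");
  std::vector<int> dx, dy, dz;
  neighbour_offsets(6, dx, dy, dz);

  IntegerVector lab(n, 0);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
  unsigned long long counter = 0;

  for (R_xlen_t s = 0; s < n; ++s) {
    if (seeds[s] > 0) {
      if (!mask[s]) stop("seed voxel outside mask");
      lab[s] = seeds[s];
    }
  }
  for (R_xlen_t s = 0; s < n; ++s) {
    if (lab[s] == 0) continue;
    int i = (int)(s % nx);
    int j = (int)((s / nx) % ny);
    int k = (int)(s / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (mask[w] && lab[w] == 0) {
        pq.push(WsEntry{relief[w], w, counter++, lab[s]});
      }
    }
  }
  while (!pq.empty()) {
    WsEntry e = pq.top();
    pq.pop();
    if (lab[e.idx] != 0) continue;
    lab[e.idx] = e.label;
    int i = (int)(e.idx % nx);
    int j = (int)((e.idx / nx) % ny);
    int k = (int)(e.idx / ((R_xlen_t)nx * ny));
    for (int t = 0; t < 6; ++t) {
      int ii = i + dx[t], jj = j + dy[t], kk = k + dz[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
      if (mask[w] && lab[w] == 0) {
        pq.push(WsEntry{relief[w], w, counter++, e.label});
      }
    }
  }
  return lab;
}
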