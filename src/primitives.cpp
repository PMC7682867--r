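// 3D image primitives: exact Euclidean distance transform (Felzenszwalb &
// Huttenlocher lower-envelope algorithm, anisotropic spacing), 6-connected
// component labelling, seeded watershed by priority flood, grey-scale ball
// erosion/dilation, separable Gaussian blur, 26-neighbourhood local maxima.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::max() / 4.0;

// 1D squared distance transform along a line of n samples spaced h apart.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double h) {
  const double pinf = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -pinf;  // true sentinels: intersections are always finite
  z[1] = pinf;
  for (int q = 1; q < n; q++) {
    double qq = q * h;
    double vv = v[k] * h;
    double s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
    while (s <= z[k]) {
      k--;
      vv = v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * (qq - vv));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = pinf;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = q * h;
    while (z[k + 1] < qq) k++;
    double vv = v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d_cpp(LogicalVector feature, IntegerVector dims,
                        NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector D(n);
  for (R_xlen_t i = 0; i < n; i++) D[i] = feature[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; x++) f[x] = D[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; x++) D[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; y++) f[y] = D[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; y++) D[base + (R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; z++) f[z] = D[base + (R_xlen_t)z * plane];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; z++) D[base + (R_xlen_t)z * plane] = d[z];
    }
  for (R_xlen_t i = 0; i < n; i++)
    D[i] = (D[i] >= INF / 2.0) ? R_PosInf : std::sqrt(D[i]);
  D.attr("dim") = dims;
  return D;
}

// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i] != 0) continue;
    next++;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t c = stack.back();
      stack.pop_back();
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / plane);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; k++) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t j = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx;
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

struct WsNode {
  double prio;
  R_xlen_t order;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on priority
    return a.order > b.order;                      // FIFO on ties
  }
};

// Seeded watershed: grow seed labels through mask in order of decreasing
// priority (here, the distance transform). Deterministic: ties broken by
// insertion order.
// [[Rcpp::export(name = ".watershed3d")]]
IntegerVector watershed3d_cpp(NumericVector priority, LogicalVector mask,
                              IntegerVector seeds, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  R_xlen_t order = 0;
  for (R_xlen_t i = 0; i < n; i++) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push({priority[i], order++, i});
    }
  }
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    R_xlen_t c = nd.idx;
    int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / plane);
    for (int k = 0; k < 6; k++) {
      int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t j = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx;
      if (mask[j] && lab[j] == 0) {
        lab[j] = lab[c];
        pq.push({priority[j], order++, j});
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 1D erosion (useMin) / dilation along x with window half-length l, borders
// treated as +/-Inf (ignored). van Herk / Gil-Werman two-scan, O(1)/sample.
static void line_min_x(const double* in, double* out, int n, int l,
                       bool useMin, std::vector<double>& g,
                       std::vector<double>& h) {
  const int w = 2 * l + 1;
  const double pad = useMin ? INF : -INF;
  const int np = ((n + w - 1) / w) * w;
  if ((int)g.size() < np) {
    g.resize(np);
    h.resize(np);
  }
  for (int i = 0; i < np; i++) {
    double v = (i < n) ? in[i] : pad;
    g[i] = (i % w == 0) ? v
                        : (useMin ? std::min(g[i - 1], v)
                                  : std::max(g[i - 1], v));
  }
  for (int i = np - 1; i >= 0; i--) {
    double v = (i < n) ? in[i] : pad;
    h[i] = ((i + 1) % w == 0) ? v
                              : (useMin ? std::min(h[i + 1], v)
                                        : std::max(h[i + 1], v));
  }
  for (int i = 0; i < n; i++) {
    int a = i - l, b = i + l;
    double va = (a >= 0) ? h[a] : pad;
    double vb = (b < np) ? g[b] : pad;
    out[i] = useMin ? std::min(va, vb) : std::max(va, vb);
  }
}

// Grey-scale erosion (op = 0) / dilation (op = 1) with an ellipsoidal
// structuring element of voxel radii (rx, ry, rz); out-of-volume samples
// are ignored (treated as +Inf for erosion, -Inf for dilation). The ball is
// decomposed exactly into x-segments: for each in-ball (dy, dz) offset the
// row contributes a segment of half-length floor(rx * sqrt(1 - (dy/ry)^2 -
// (dz/rz)^2)); segment erosions are shared across offsets with equal length.
// [[Rcpp::export(name = ".morphBall3d")]]
NumericVector morph_ball3d_cpp(NumericVector img, IntegerVector dims,
                               NumericVector radii, int op) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const R_xlen_t n = plane * nz;
  const bool useMin = (op == 0);
  const int ry = (int)std::floor(radii[1]);
  const int rz = (int)std::floor(radii[2]);
  // group (dy, dz) offsets by segment half-length
  std::vector<std::vector<std::pair<int, int> > > groups;
  std::vector<int> lens;
  for (int dz = -rz; dz <= rz; dz++)
    for (int dy = -ry; dy <= ry; dy++) {
      double u = radii[1] > 0 ? (double)dy / radii[1] : 0.0;
      double v = radii[2] > 0 ? (double)dz / radii[2] : 0.0;
      double rem = 1.0 - u * u - v * v;
      if (rem < -1e-12) continue;
      int l = (int)std::floor(radii[0] * std::sqrt(std::max(rem, 0.0)));
      size_t gi;
      for (gi = 0; gi < lens.size(); gi++)
        if (lens[gi] == l) break;
      if (gi == lens.size()) {
        lens.push_back(l);
        groups.push_back(std::vector<std::pair<int, int> >());
      }
      groups[gi].push_back(std::make_pair(dy, dz));
    }
  NumericVector out(n);
  const double pad = useMin ? INF : -INF;
  for (R_xlen_t i = 0; i < n; i++) out[i] = pad;
  std::vector<double> E(n), g, h;
  for (size_t gi = 0; gi < lens.size(); gi++) {
    const int l = lens[gi];
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++) {
        const double* row = &img[(R_xlen_t)z * plane + (R_xlen_t)y * nx];
        double* erow = &E[(R_xlen_t)z * plane + (R_xlen_t)y * nx];
        line_min_x(row, erow, nx, l, useMin, g, h);
      }
    for (size_t k = 0; k < groups[gi].size(); k++) {
      const int dy = groups[gi][k].first, dz = groups[gi][k].second;
      const int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
      const int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
      for (int z = z0; z < z1; z++)
        for (int y = y0; y < y1; y++) {
          const double* src =
              &E[(R_xlen_t)(z + dz) * plane + (R_xlen_t)(y + dy) * nx];
          double* dst = &out[(R_xlen_t)z * plane + (R_xlen_t)y * nx];
          if (useMin) {
            for (int x = 0; x < nx; x++)
              if (src[x] < dst[x]) dst[x] = src[x];
          } else {
            for (int x = 0; x < nx; x++)
              if (src[x] > dst[x]) dst[x] = src[x];
          }
        }
    }
  }
  out.attr("dim") = dims;
  return out;
}

static void blur_axis(std::vector<double>& buf, NumericVector& img, int nx,
                      int ny, int nz, int axis, const std::vector<double>& ker) {
  const int r = (int)(ker.size() - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  const R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nx : plane;
  const int n1 = (axis == 0) ? ny : nx;
  const int n2 = (axis == 2) ? ny : nz;
  buf.resize(len);
  for (int b = 0; b < n2; b++)
    for (int a = 0; a < n1; a++) {
      R_xlen_t base;
      if (axis == 0)
        base = (R_xlen_t)b * plane + (R_xlen_t)a * nx;
      else if (axis == 1)
        base = (R_xlen_t)b * plane + a;
      else
        base = (R_xlen_t)b * nx + a;
      for (int i = 0; i < len; i++) buf[i] = img[base + (R_xlen_t)i * stride];
      for (int i = 0; i < len; i++) {
        double s = 0.0;
        for (int k = -r; k <= r; k++) {
          int j = i + k;
          if (j < 0) j = -j - 1;            // reflect
          if (j >= len) j = 2 * len - j - 1;
          s += ker[k + r] * buf[j];
        }
        img[base + (R_xlen_t)i * stride] = s;
      }
    }
}

// [[Rcpp::export(name = ".gaussBlur3d")]]
NumericVector gauss_blur3d_cpp(NumericVector img, IntegerVector dims,
                               double sigma) {
  NumericVector out = clone(img);
  if (sigma <= 0) {
    out.attr("dim") = dims;
    return out;
  }
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; k++) {
    ker[k + r] = std::exp(-0.5 * k * k / (sigma * sigma));
    s += ker[k + r];
  }
  for (auto& v : ker) v /= s;
  std::vector<double> buf;
  blur_axis(buf, out, dims[0], dims[1], dims[2], 0, ker);
  blur_axis(buf, out, dims[0], dims[1], dims[2], 1, ker);
  blur_axis(buf, out, dims[0], dims[1], dims[2], 2, ker);
  out.attr("dim") = dims;
  return out;
}

// Indices (1-based, column-major) of voxels that are >= all of their 26
// neighbours, above `threshold`, and inside `mask`.
// [[Rcpp::export(name = ".localMaxima3d")]]
IntegerVector local_maxima3d_cpp(NumericVector x, LogicalVector mask,
                                 IntegerVector dims, double threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  std::vector<int> out;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int xx = 0; xx < nx; xx++) {
        R_xlen_t i = (R_xlen_t)z * plane + (R_xlen_t)y * nx + xx;
        if (!mask[i] || x[i] <= threshold) continue;
        bool ok = true;
        for (int dz = -1; dz <= 1 && ok; dz++)
          for (int dy = -1; dy <= 1 && ok; dy++)
            for (int dx = -1; dx <= 1 && ok; dx++) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int ax = xx + dx, ay = y + dy, az = z + dz;
              if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 ||
                  az >= nz)
                continue;
              if (x[(R_xlen_t)az * plane + (R_xlen_t)ay * nx + ax] > x[i])
                ok = false;
            }
        if (ok) out.push_back((int)i + 1);
      }
  return wrap(out);
}
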