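// Low-level raster operations shared by the preprocessing, inference and
// metrics modules. All 3-D arrays follow the package-wide (z, y, x) axis
// order; R stores them column-major so z is the fastest-varying index and
// the linear offset of voxel (z, y, x) is z + nz*(y + ny*x).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear or nearest-neighbour resize of a 2-D matrix to (out_h, out_w)
// using the half-pixel-centre convention, so identical sizes round-trip
// exactly and constants are preserved.
// [[Rcpp::export(name = ".cpp_resize2d")]]
NumericMatrix cpp_resize2d(const NumericMatrix& src, int out_h, int out_w,
                           bool nearest) {
  const int in_h = src.nrow(), in_w = src.ncol();
  if (in_h < 1 || in_w < 1 || out_h < 1 || out_w < 1)
    stop("resize: empty input or output");
  NumericMatrix out(out_h, out_w);
  const double sy = (double)in_h / out_h, sx = (double)in_w / out_w;
  for (int j = 0; j < out_w; ++j) {
    double xs = (j + 0.5) * sx - 0.5;
    for (int i = 0; i < out_h; ++i) {
      double ys = (i + 0.5) * sy - 0.5;
      if (nearest) {
        int yi = (int)clampd(std::floor(ys + 0.5), 0, in_h - 1);
        int xi = (int)clampd(std::floor(xs + 0.5), 0, in_w - 1);
        out(i, j) = src(yi, xi);
      } else {
        double yc = clampd(ys, 0, in_h - 1), xc = clampd(xs, 0, in_w - 1);
        int y0 = (int)std::floor(yc), x0 = (int)std::floor(xc);
        int y1 = std::min(y0 + 1, in_h - 1), x1 = std::min(x0 + 1, in_w - 1);
        double fy = yc - y0, fx = xc - x0;
        out(i, j) = (1 - fy) * ((1 - fx) * src(y0, x0) + fx * src(y0, x1)) +
                    fy * ((1 - fx) * src(y1, x0) + fx * src(y1, x1));
      }
    }
  }
  return out;
}

// Backward warp: for every output pixel, rotate (about the image centre,
// `angle` in radians) and shift by a dense displacement field, then sample
// the source. Used for augmentation; bilinear for images, nearest for labels.
// Out-of-bounds samples take `fill`.
// [[Rcpp::export(name = ".cpp_warp2d")]]
NumericMatrix cpp_warp2d(const NumericMatrix& src, double angle,
                         const NumericMatrix& dy, const NumericMatrix& dx,
                         bool nearest, double fill) {
  const int h = src.nrow(), w = src.ncol();
  if (dy.nrow() != h || dy.ncol() != w || dx.nrow() != h || dx.ncol() != w)
    stop("warp: displacement field shape mismatch");
  NumericMatrix out(h, w);
  const double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  const double ca = std::cos(angle), sa = std::sin(angle);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double ry = ca * (i - cy) - sa * (j - cx) + cy;
      double rx = sa * (i - cy) + ca * (j - cx) + cx;
      double ys = ry + dy(i, j), xs = rx + dx(i, j);
      if (nearest) {
        int yi = (int)std::floor(ys + 0.5), xi = (int)std::floor(xs + 0.5);
        out(i, j) = (yi < 0 || yi >= h || xi < 0 || xi >= w) ? fill : src(yi, xi);
      } else {
        if (ys < 0 || ys > h - 1 || xs < 0 || xs > w - 1) { out(i, j) = fill; continue; }
        int y0 = (int)std::floor(ys), x0 = (int)std::floor(xs);
        int y1 = std::min(y0 + 1, h - 1), x1 = std::min(x0 + 1, w - 1);
        double fy = ys - y0, fx = xs - x0;
        out(i, j) = (1 - fy) * ((1 - fx) * src(y0, x0) + fx * src(y0, x1)) +
                    fy * ((1 - fx) * src(y1, x0) + fx * src(y1, x1));
      }
    }
  }
  return out;
}

// 6-connected labelling of a 3-D logical array (dims nz, ny, nx).
// Components are numbered 1..k in scan order; background stays 0.
// [[Rcpp::export(name = ".cpp_label3d")]]
IntegerVector cpp_label3d(const LogicalVector& mask, int nz, int ny, int nx) {
  if ((R_xlen_t)nz * ny * nx != mask.size()) stop("label3d: dims mismatch");
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::vector<int> stack;
  for (R_xlen_t start = 0; start < mask.size(); ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    stack.push_back((int)start);
    lab[start] = next;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v % nz, rest = v / nz, y = rest % ny, x = rest / ny;
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dyv[6] = {0, 0, -1, 1, 0, 0};
      const int dxv[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int z2 = z + dz[k], y2 = y + dyv[k], x2 = x + dxv[k];
        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx) continue;
        int u = z2 + nz * (y2 + ny * x2);
        if (mask[u] && !lab[u]) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nz, ny, nx);
  return lab;
}

// Morphological dilation (or erosion) of a 3-D binary array by an arbitrary
// voxel-offset structuring element (rows of `offsets` = dz, dy, dx).
// Erosion treats voxels outside the array as background.
// [[Rcpp::export(name = ".cpp_morph3d")]]
LogicalVector cpp_morph3d(const LogicalVector& mask, int nz, int ny, int nx,
                          const IntegerMatrix& offsets, bool dilate) {
  if ((R_xlen_t)nz * ny * nx != mask.size()) stop("morph3d: dims mismatch");
  LogicalVector out(mask.size());
  const int m = offsets.nrow();
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        bool acc = dilate ? false : true;
        for (int k = 0; k < m; ++k) {
          int z2 = z + offsets(k, 0), y2 = y + offsets(k, 1), x2 = x + offsets(k, 2);
          bool v;
          if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny || x2 < 0 || x2 >= nx)
            v = false;
          else
            v = mask[z2 + nz * (y2 + ny * x2)];
          if (dilate) { if (v) { acc = true; break; } }
          else { if (!v) { acc = false; break; } }
        }
        out[z + nz * (y + ny * x)] = acc;
      }
  out.attr("dim") = IntegerVector::create(nz, ny, nx);
  return out;
}

// Exact 1-D squared-distance transform (lower-envelope algorithm) over a
// sampled grid with physical sample spacing `s`. f holds squared distances.
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  if (n == 1) return;
  std::vector<double> d(n);
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  const double INF = std::numeric_limits<double>::infinity();
  int q0 = 0;
  while (q0 < n && f[q0] == INF) ++q0;
  if (q0 == n) return; // whole line empty
  int k = 0;
  v[0] = q0; zb[0] = -INF; zb[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double sq = (double)q * s, fq = f[q];
    while (true) {
      double sv = (double)v[k] * s;
      double inter = (fq + sq * sq - (f[v[k]] + sv * sv)) / (2 * sq - 2 * sv);
      if (inter <= zb[k] && k > 0) { --k; continue; }
      if (inter <= zb[k]) { // replace the single remaining parabola
        v[0] = q; zb[0] = -INF; zb[1] = INF; break;
      }
      ++k; v[k] = q; zb[k] = inter; zb[k + 1] = INF; break;
    }
  }
  int kk = 0;
  for (int q = 0; q < n; ++q) {
    double sq = (double)q * s;
    while (zb[kk + 1] < sq) ++kk;
    double sv = (double)v[kk] * s;
    d[q] = (sq - sv) * (sq - sv) + f[v[kk]];
  }
  f.swap(d);
}

// Exact anisotropic squared Euclidean distance transform of a 3-D binary
// array: for every voxel, the squared distance (mm^2) to the nearest true
// voxel centre, with per-axis spacing (mm). Inf where the mask is empty.
// [[Rcpp::export(name = ".cpp_edt3d")]]
NumericVector cpp_edt3d(const LogicalVector& mask, int nz, int ny, int nx,
                        const NumericVector& spacing) {
  if ((R_xlen_t)nz * ny * nx != mask.size()) stop("edt3d: dims mismatch");
  if (spacing.size() != 3) stop("edt3d: spacing must have length 3");
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector f(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) f[i] = mask[i] ? 0.0 : INF;
  std::vector<double> line;
  // pass along z
  line.resize(nz);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = nz * ((R_xlen_t)y + ny * (R_xlen_t)x);
      for (int z = 0; z < nz; ++z) line[z] = f[base + z];
      dt1d(line, spacing[0]);
      for (int z = 0; z < nz; ++z) f[base + z] = line[z];
    }
  // pass along y
  line.resize(ny);
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) line[y] = f[z + nz * ((R_xlen_t)y + ny * (R_xlen_t)x)];
      dt1d(line, spacing[1]);
      for (int y = 0; y < ny; ++y) f[z + nz * ((R_xlen_t)y + ny * (R_xlen_t)x)] = line[y];
    }
  // pass along x
  line.resize(nx);
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) line[x] = f[z + nz * ((R_xlen_t)y + ny * (R_xlen_t)x)];
      dt1d(line, spacing[2]);
      for (int x = 0; x < nx; ++x) f[z + nz * ((R_xlen_t)y + ny * (R_xlen_t)x)] = line[x];
    }
  f.attr("dim") = IntegerVector::create(nz, ny, nx);
  return f;
}
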