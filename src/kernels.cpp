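#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// 3D index helpers: volumes are R arrays, column-major, dims (nx, ny, nz).
static inline R_xlen_t idx3(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * z);
}

// Label 6-connected components of a binary volume. Labels start at 1,
// 0 = background. BFS; deterministic label order (scan order of seeds).
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t c = q.front(); q.pop();
      int z = c / ((R_xlen_t)nx * ny);
      R_xlen_t r = c - (R_xlen_t)z * nx * ny;
      int y = r / nx, x = r % nx;
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t t = idx3(xx, yy, zz, nx, ny);
        if (mask[t] && !lab[t]) { lab[t] = next; q.push(t); }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// One pass of 6-neighbourhood binary dilation (or erosion via complement).
// [[Rcpp::export(name = ".binary_dilate3d")]]
LogicalVector binary_dilate3d(LogicalVector mask, IntegerVector dim,
                              int iterations) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalVector nxt = clone(cur);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t c = idx3(x, y, z, nx, ny);
          if (cur[c]) continue;
          bool hit =
            (x > 0      && cur[idx3(x - 1, y, z, nx, ny)]) ||
            (x < nx - 1 && cur[idx3(x + 1, y, z, nx, ny)]) ||
            (y > 0      && cur[idx3(x, y - 1, z, nx, ny)]) ||
            (y < ny - 1 && cur[idx3(x, y + 1, z, nx, ny)]) ||
            (z > 0      && cur[idx3(x, y, z - 1, nx, ny)]) ||
            (z < nz - 1 && cur[idx3(x, y, z + 1, nx, ny)]);
          if (hit) nxt[c] = true;
        }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export(name = ".binary_erode3d")]]
LogicalVector binary_erode3d(LogicalVector mask, IntegerVector dim,
                             int iterations) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector cur = clone(mask);
  for (int it = 0; it < iterations; ++it) {
    LogicalVector nxt = clone(cur);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t c = idx3(x, y, z, nx, ny);
          if (!cur[c]) continue;
          bool miss =
            (x == 0      || !cur[idx3(x - 1, y, z, nx, ny)]) ||
            (x == nx - 1 || !cur[idx3(x + 1, y, z, nx, ny)]) ||
            (y == 0      || !cur[idx3(x, y - 1, z, nx, ny)]) ||
            (y == ny - 1 || !cur[idx3(x, y + 1, z, nx, ny)]) ||
            (z == 0      || !cur[idx3(x, y, z - 1, nx, ny)]) ||
            (z == nz - 1 || !cur[idx3(x, y, z + 1, nx, ny)]);
          if (miss) nxt[c] = false;
        }
    cur = nxt;
  }
  return cur;
}

// Trilinear (or nearest-neighbour) resampling on an index-space grid.
// Output voxel i maps to input coordinate i * (out_spacing / in_spacing);
// edge-clamped.
// [[Rcpp::export(name = ".resample3d")]]
NumericVector resample3d(NumericVector vol, IntegerVector dim,
                         NumericVector ratio, IntegerVector outdim,
                         bool nearest) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int ox = outdim[0], oy = outdim[1], oz = outdim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  for (int z = 0; z < oz; ++z) {
    double fz = z * ratio[2];
    if (fz > nz - 1) fz = nz - 1;
    int z0 = (int)std::floor(fz), z1 = std::min(z0 + 1, nz - 1);
    double wz = fz - z0;
    for (int y = 0; y < oy; ++y) {
      double fy = y * ratio[1];
      if (fy > ny - 1) fy = ny - 1;
      int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, ny - 1);
      double wy = fy - y0;
      for (int x = 0; x < ox; ++x) {
        double fx = x * ratio[0];
        if (fx > nx - 1) fx = nx - 1;
        int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, nx - 1);
        double wx = fx - x0;
        double v;
        if (nearest) {
          v = vol[idx3((int)std::lround(fx), (int)std::lround(fy),
                       (int)std::lround(fz), nx, ny)];
        } else {
          double c00 = vol[idx3(x0, y0, z0, nx, ny)] * (1 - wx) +
                       vol[idx3(x1, y0, z0, nx, ny)] * wx;
          double c10 = vol[idx3(x0, y1, z0, nx, ny)] * (1 - wx) +
                       vol[idx3(x1, y1, z0, nx, ny)] * wx;
          double c01 = vol[idx3(x0, y0, z1, nx, ny)] * (1 - wx) +
                       vol[idx3(x1, y0, z1, nx, ny)] * wx;
          double c11 = vol[idx3(x0, y1, z1, nx, ny)] * (1 - wx) +
                       vol[idx3(x1, y1, z1, nx, ny)] * wx;
          double c0 = c00 * (1 - wy) + c10 * wy;
          double c1 = c01 * (1 - wy) + c11 * wy;
          v = c0 * (1 - wz) + c1 * wz;
        }
        out[idx3(x, y, z, ox, oy)] = v;
      }
    }
  }
  return out;
}

// Bilinear resize of a 2D matrix to out_r x out_c (aspect not preserved).
// [[Rcpp::export(name = ".resize_bilinear")]]
NumericMatrix resize_bilinear(NumericMatrix img, int out_r, int out_c) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(out_r, out_c);
  double sr = (out_r > 1) ? (double)(nr - 1) / (out_r - 1) : 0.0;
  double sc = (out_c > 1) ? (double)(nc - 1) / (out_c - 1) : 0.0;
  for (int j = 0; j < out_c; ++j) {
    double fc = j * sc;
    int c0 = (int)std::floor(fc), c1 = std::min(c0 + 1, nc - 1);
    double wc = fc - c0;
    for (int i = 0; i < out_r; ++i) {
      double fr = i * sr;
      int r0 = (int)std::floor(fr), r1 = std::min(r0 + 1, nr - 1);
      double wr = fr - r0;
      out(i, j) = img(r0, c0) * (1 - wr) * (1 - wc) +
                  img(r1, c0) * wr * (1 - wc) +
                  img(r0, c1) * (1 - wr) * wc +
                  img(r1, c1) * wr * wc;
    }
  }
  return out;
}

// Rotate a 2D matrix by angle_deg (counter-clockwise) about its centre,
// bilinear interpolation, out-of-range pixels take `fill`.
// [[Rcpp::export(name = ".rotate_bilinear")]]
NumericMatrix rotate_bilinear(NumericMatrix img, double angle_deg,
                              double fill) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  double th = angle_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      // inverse map: output (i,j) pulled from input coordinates
      double dr = i - cr, dc = j - cc;
      double fr = cr + ct * dr + st * dc;
      double fc = cc - st * dr + ct * dc;
      if (fr < 0 || fr > nr - 1 || fc < 0 || fc > nc - 1) {
        out(i, j) = fill;
        continue;
      }
      int r0 = (int)std::floor(fr), r1 = std::min(r0 + 1, nr - 1);
      int c0 = (int)std::floor(fc), c1 = std::min(c0 + 1, nc - 1);
      double wr = fr - r0, wc = fc - c0;
      out(i, j) = img(r0, c0) * (1 - wr) * (1 - wc) +
                  img(r1, c0) * wr * (1 - wc) +
                  img(r0, c1) * (1 - wr) * wc +
                  img(r1, c1) * wr * wc;
    }
  return out;
}

// Block-mean pooling of a 2D matrix down to grid x grid cells.
// [[Rcpp::export(name = ".pool_mean2d")]]
NumericVector pool_mean2d(NumericMatrix img, int grid) {
  int nr = img.nrow(), nc = img.ncol();
  NumericVector out(grid * grid);
  for (int gj = 0; gj < grid; ++gj) {
    int c0 = (int)std::floor((double)gj * nc / grid);
    int c1 = (int)std::floor((double)(gj + 1) * nc / grid);
    if (c1 <= c0) c1 = c0 + 1;
    for (int gi = 0; gi < grid; ++gi) {
      int r0 = (int)std::floor((double)gi * nr / grid);
      int r1 = (int)std::floor((double)(gi + 1) * nr / grid);
      if (r1 <= r0) r1 = r0 + 1;
      double s = 0;
      for (int j = c0; j < c1; ++j)
        for (int i = r0; i < r1; ++i) s += img(i, j);
      out[gi + grid * gj] = s / ((double)(r1 - r0) * (c1 - c0));
    }
  }
  return out;
}

// Block-max pooling of a 2D matrix down to grid x grid cells.
// [[Rcpp::export(name = ".pool_max2d")]]
NumericVector pool_max2d(NumericMatrix img, int grid) {
  int nr = img.nrow(), nc = img.ncol();
  NumericVector out(grid * grid);
  for (int gj = 0; gj < grid; ++gj) {
    int c0 = (int)std::floor((double)gj * nc / grid);
    int c1 = (int)std::floor((double)(gj + 1) * nc / grid);
    if (c1 <= c0) c1 = c0 + 1;
    for (int gi = 0; gi < grid; ++gi) {
      int r0 = (int)std::floor((double)gi * nr / grid);
      int r1 = (int)std::floor((double)(gi + 1) * nr / grid);
      if (r1 <= r0) r1 = r0 + 1;
      double m = img(r0, c0);
      for (int j = c0; j < c1; ++j)
        for (int i = r0; i < r1; ++i)
          if (img(i, j) > m) m = img(i, j);
      out[gi + grid * gj] = m;
    }
  }
  return out;
}
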