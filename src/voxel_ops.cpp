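#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

static inline int reflect_idx(int i, int n) {
  // reflect-101 boundary: ... 2 1 | 0 1 2 ... n-1 | n-2 n-3 ...
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Separable 3D convolution with reflected boundaries. Kernels are centred
// (odd length assumed); an empty kernel skips the corresponding axis.
// [[Rcpp::export(name = ".conv3d_sep")]]
NumericVector conv3d_sep(NumericVector arr, NumericVector kx,
                         NumericVector ky, NumericVector kz) {
  IntegerVector d = arr.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = arr.size();
  std::vector<double> cur(arr.begin(), arr.end()), nxt(n);

  // pass along x
  if (kx.size() > 0) {
    const int m = kx.size(), c = m / 2;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y) {
        const R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; ++x) {
          double s = 0.0;
          for (int t = 0; t < m; ++t)
            s += kx[t] * cur[base + reflect_idx(x + t - c, nx)];
          nxt[base + x] = s;
        }
      }
    cur.swap(nxt);
  }
  // pass along y
  if (ky.size() > 0) {
    const int m = ky.size(), c = m / 2;
    for (int z = 0; z < nz; ++z)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; ++y) {
          double s = 0.0;
          for (int t = 0; t < m; ++t)
            s += ky[t] * cur[base + (R_xlen_t)reflect_idx(y + t - c, ny) * nx];
          nxt[base + (R_xlen_t)y * nx] = s;
        }
      }
    cur.swap(nxt);
  }
  // pass along z
  if (kz.size() > 0) {
    const int m = kz.size(), c = m / 2;
    const R_xlen_t plane = (R_xlen_t)nx * ny;
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        const R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; ++z) {
          double s = 0.0;
          for (int t = 0; t < m; ++t)
            s += kz[t] * cur[base + (R_xlen_t)reflect_idx(z + t - c, nz) * plane];
          nxt[base + (R_xlen_t)z * plane] = s;
        }
      }
    cur.swap(nxt);
  }

  NumericVector out(cur.begin(), cur.end());
  out.attr("dim") = d;
  return out;
}

// 6-connected component labelling of a binary volume.
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = mask.size(), plane = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  lab.attr("dim") = d;
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int x = v % nx, y = (v / nx) % ny, z = v / plane;
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        int xx = x + dx[t], yy = y + dy[t], zz = z + dz[t];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx;
        if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// Strict-ish 26-neighbourhood local maxima above a threshold, optionally
// restricted to a mask. Returns 1-based voxel indices, one row per maximum.
// [[Rcpp::export(name = ".local_maxima3d")]]
IntegerMatrix local_maxima3d(NumericVector arr, double threshold,
                             LogicalVector mask) {
  IntegerVector d = arr.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  const bool use_mask = mask.size() == arr.size();
  std::vector<int> xs, ys, zs;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = (R_xlen_t)z * plane + (R_xlen_t)y * nx + x;
        double val = arr[v];
        if (val <= threshold) continue;
        if (use_mask && !mask[v]) continue;
        bool is_max = true;
        for (int dz2 = -1; dz2 <= 1 && is_max; ++dz2)
          for (int dy2 = -1; dy2 <= 1 && is_max; ++dy2)
            for (int dx2 = -1; dx2 <= 1 && is_max; ++dx2) {
              if (!dx2 && !dy2 && !dz2) continue;
              int xx = x + dx2, yy = y + dy2, zz = z + dz2;
              if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
              R_xlen_t w = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx;
              if (arr[w] > val) is_max = false;
              // plateau tie-break: keep the lexicographically first voxel
              if (arr[w] == val && w < v) is_max = false;
            }
        if (is_max) { xs.push_back(x + 1); ys.push_back(y + 1); zs.push_back(z + 1); }
      }
  IntegerMatrix out(xs.size(), 3);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i]; out(i, 1) = ys[i]; out(i, 2) = zs[i];
  }
  return out;
}

// Box binary dilation by r voxels along each axis (separable max filter).
// [[Rcpp::export(name = ".dilate3d")]]
LogicalVector dilate3d(LogicalVector mask, int r) {
  IntegerVector d = mask.attr("dim");
  const int nx = d[0], ny = d[1], nz = d[2];
  const R_xlen_t n = mask.size(), plane = (R_xlen_t)nx * ny;
  std::vector<char> cur(mask.begin(), mask.end()), nxt(n);
  const int dims[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, plane};
  for (int ax = 0; ax < 3; ++ax) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t v = (R_xlen_t)z * plane + (R_xlen_t)y * nx + x;
          int pos = ax == 0 ? x : (ax == 1 ? y : z);
          char any = 0;
          for (int t = -r; t <= r && !any; ++t) {
            int p = pos + t;
            if (p < 0 || p >= dims[ax]) continue;
            any = cur[v + (R_xlen_t)(p - pos) * strides[ax]];
          }
          nxt[v] = any;
        }
    cur.swap(nxt);
  }
  LogicalVector out(cur.begin(), cur.end());
  out.attr("dim") = d;
  return out;
}

// Voxel classification of a deformed-ellipsoid nucleus on a regular grid:
// 0 = outside, 1 = nuclear lumen, 2 = inside a nucleolus. rot maps body to
// lab coordinates; nucleoli rows are (x, y, z, radius) offsets from centre.
// [[Rcpp::export(name = ".nucleus_mask_codes")]]
IntegerVector nucleus_mask_codes(IntegerVector dims, NumericVector origin,
                                 NumericVector spacing, NumericVector center,
                                 NumericMatrix rot, NumericVector semi,
                                 double amp, NumericMatrix freqs,
                                 NumericVector phases, NumericVector coefs,
                                 double norm, NumericMatrix nucleoli) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int K = freqs.nrow(), nnuc = nucleoli.nrow();
  IntegerVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dims;
  R_xlen_t v = 0;
  for (int z = 0; z < nz; ++z) {
    double pz = origin[2] + (z + 0.5) * spacing[2] - center[2];
    for (int y = 0; y < ny; ++y) {
      double py = origin[1] + (y + 0.5) * spacing[1] - center[1];
      for (int x = 0; x < nx; ++x, ++v) {
        double px = origin[0] + (x + 0.5) * spacing[0] - center[0];
        double bx = rot(0, 0) * px + rot(1, 0) * py + rot(2, 0) * pz;
        double by = rot(0, 1) * px + rot(1, 1) * py + rot(2, 1) * pz;
        double bz = rot(0, 2) * px + rot(1, 2) * py + rot(2, 2) * pz;
        double ex = bx / semi[0], ey = by / semi[1], ez = bz / semi[2];
        double nn = std::sqrt(ex * ex + ey * ey + ez * ez);
        double f = 1.0;
        if (amp > 0 && nn > 0) {
          double ux = ex / nn, uy = ey / nn, uz = ez / nn, g = 0.0;
          for (int k = 0; k < K; ++k)
            g += coefs[k] * std::cos(freqs(k, 0) * ux + freqs(k, 1) * uy +
                                     freqs(k, 2) * uz + phases[k]);
          f = 1.0 + amp * g / norm;
        }
        if (nn > f) { out[v] = 0; continue; }
        int code = 1;
        for (int q = 0; q < nnuc; ++q) {
          double dx2 = px - nucleoli(q, 0), dy2 = py - nucleoli(q, 1),
                 dz2 = pz - nucleoli(q, 2);
          if (dx2 * dx2 + dy2 * dy2 + dz2 * dz2 <
              nucleoli(q, 3) * nucleoli(q, 3)) { code = 2; break; }
        }
        out[v] = code;
      }
    }
  }
  return out;
}

// Trilinear interpolation of a coarse noise grid at every voxel centre.
// [[Rcpp::export(name = ".texture_on_grid")]]
NumericVector texture_on_grid(IntegerVector dims, NumericVector origin,
                              NumericVector spacing, NumericVector grid,
                              NumericVector lo, double scale) {
  IntegerVector gd = grid.attr("dim");
  const int gx = gd[0], gy = gd[1], gz = gd[2];
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dims;
  R_xlen_t v = 0;
  const R_xlen_t gplane = (R_xlen_t)gx * gy;
  for (int z = 0; z < nz; ++z) {
    double tz = (origin[2] + (z + 0.5) * spacing[2] - lo[2]) / scale;
    int k0 = std::min(std::max((int)std::floor(tz), 0), gz - 2);
    double fz = tz - k0;
    for (int y = 0; y < ny; ++y) {
      double ty = (origin[1] + (y + 0.5) * spacing[1] - lo[1]) / scale;
      int j0 = std::min(std::max((int)std::floor(ty), 0), gy - 2);
      double fy = ty - j0;
      for (int x = 0; x < nx; ++x, ++v) {
        double tx = (origin[0] + (x + 0.5) * spacing[0] - lo[0]) / scale;
        int i0 = std::min(std::max((int)std::floor(tx), 0), gx - 2);
        double fx = tx - i0;
        const double *g000 = &grid[(R_xlen_t)k0 * gplane + (R_xlen_t)j0 * gx + i0];
        double c00 = g000[0] * (1 - fx) + g000[1] * fx;
        double c10 = g000[gx] * (1 - fx) + g000[gx + 1] * fx;
        double c01 = g000[gplane] * (1 - fx) + g000[gplane + 1] * fx;
        double c11 = g000[gplane + gx] * (1 - fx) + g000[gplane + gx + 1] * fx;
        out[v] = (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
                 (c01 * (1 - fy) + c11 * fy) * fz;
      }
    }
  }
  return out;
}
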