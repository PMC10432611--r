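// Low-level array kernels: separable Gaussian smoothing, connected
// components, ball-structuring-element morphology, trilinear resampling,
// affine warping, and im2col/col2im for 3D convolution. All grids are
// column-major R arrays indexed (x, y, z), 0-based in C++.

#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Separable Gaussian filter applied independently to each axial (z) slice.
// sigma in voxels; kernel truncated at 4 sigma. sigma <= 0 returns input.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth2d(NumericVector vol, double sigma) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  if (sigma <= 0) return clone(vol);
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double &v : k) v /= s;

  NumericVector out(vol.size());
  out.attr("dim") = d;
  std::vector<double> tmp((size_t)nx * ny);
  for (int z = 0; z < nz; ++z) {
    const double *src = vol.begin() + (size_t)nx * ny * z;
    double *dst = out.begin() + (size_t)nx * ny * z;
    // along x (replicate border)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int xx = std::min(std::max(x + i, 0), nx - 1);
          acc += k[i + r] * src[xx + nx * y];
        }
        tmp[x + nx * y] = acc;
      }
    // along y
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int i = -r; i <= r; ++i) {
          int yy = std::min(std::max(y + i, 0), ny - 1);
          acc += k[i + r] * tmp[x + nx * yy];
        }
        dst[x + nx * y] = acc;
      }
  }
  return out;
}

// 2D connected-component labelling of one slice (8-connectivity).
// [[Rcpp::export]]
IntegerMatrix cpp_label2d(LogicalMatrix m) {
  int nx = m.nrow(), ny = m.ncol();
  IntegerMatrix lab(nx, ny);
  int cur = 0;
  std::queue<std::pair<int, int> > q;
  for (int y0 = 0; y0 < ny; ++y0)
    for (int x0 = 0; x0 < nx; ++x0) {
      if (!m(x0, y0) || lab(x0, y0)) continue;
      ++cur;
      lab(x0, y0) = cur;
      q.push(std::make_pair(x0, y0));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy) continue;
            int x = p.first + dx, y = p.second + dy;
            if (x < 0 || y < 0 || x >= nx || y >= ny) continue;
            if (m(x, y) && !lab(x, y)) {
              lab(x, y) = cur;
              q.push(std::make_pair(x, y));
            }
          }
      }
    }
  return lab;
}

// 3D connected-component labelling (6-connectivity).
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  IntegerVector lab(mask.size());
  lab.attr("dim") = d;
  const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                         {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
  int cur = 0;
  std::queue<int> q;
  for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int x0 = 0; x0 < nx; ++x0) {
        int i0 = idx3(x0, y0, z0, nx, ny);
        if (!mask[i0] || lab[i0]) continue;
        ++cur;
        lab[i0] = cur;
        q.push(i0);
        while (!q.empty()) {
          int i = q.front();
          q.pop();
          int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
          for (int k = 0; k < 6; ++k) {
            int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int j = idx3(xx, yy, zz, nx, ny);
            if (mask[j] && !lab[j]) {
              lab[j] = cur;
              q.push(j);
            }
          }
        }
      }
  return lab;
}

// Ball-structuring-element morphology; dilate = true for dilation,
// false for erosion (erosion treats outside the grid as background).
// [[Rcpp::export]]
LogicalVector cpp_morph3d(LogicalVector mask, double radius, bool dilate) {
  IntegerVector d = mask.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int r = (int)std::floor(radius);
  std::vector<int> ox, oy, oz;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= radius * radius) {
          ox.push_back(dx);
          oy.push_back(dy);
          oz.push_back(dz);
        }
  int m = ox.size();
  LogicalVector out(mask.size());
  out.attr("dim") = d;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        bool v = dilate ? false : true;
        for (int k = 0; k < m; ++k) {
          int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
          bool in = (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny &&
                     zz < nz) ? (bool)mask[idx3(xx, yy, zz, nx, ny)] : false;
          if (dilate) {
            if (in) { v = true; break; }
          } else {
            if (!in) { v = false; break; }
          }
        }
        out[idx3(x, y, z, nx, ny)] = v;
      }
  return out;
}

static inline double tri_sample(const double *v, int nx, int ny, int nz,
                                double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return fill;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
      z1 = std::min(z0 + 1, nz - 1);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double c00 = v[idx3(x0, y0, z0, nx, ny)] * (1 - fx) +
               v[idx3(x1, y0, z0, nx, ny)] * fx;
  double c10 = v[idx3(x0, y1, z0, nx, ny)] * (1 - fx) +
               v[idx3(x1, y1, z0, nx, ny)] * fx;
  double c01 = v[idx3(x0, y0, z1, nx, ny)] * (1 - fx) +
               v[idx3(x1, y0, z1, nx, ny)] * fx;
  double c11 = v[idx3(x0, y1, z1, nx, ny)] * (1 - fx) +
               v[idx3(x1, y1, z1, nx, ny)] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Resample to a new grid, corner voxel centres aligned.
// order 0 = nearest neighbour, order 1 = trilinear.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector vol, IntegerVector target,
                             int order) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int tx = target[0], ty = target[1], tz = target[2];
  NumericVector out((size_t)tx * ty * tz);
  out.attr("dim") = IntegerVector::create(tx, ty, tz);
  double sx = tx > 1 ? (double)(nx - 1) / (tx - 1) : 0.0;
  double sy = ty > 1 ? (double)(ny - 1) / (ty - 1) : 0.0;
  double sz = tz > 1 ? (double)(nz - 1) / (tz - 1) : 0.0;
  const double *v = vol.begin();
  for (int z = 0; z < tz; ++z)
    for (int y = 0; y < ty; ++y)
      for (int x = 0; x < tx; ++x) {
        double px = x * sx, py = y * sy, pz = z * sz;
        double val;
        if (order == 0) {
          int xx = (int)std::round(px), yy = (int)std::round(py),
              zz = (int)std::round(pz);
          val = v[idx3(xx, yy, zz, nx, ny)];
        } else {
          val = tri_sample(v, nx, ny, nz, px, py, pz, 0.0);
        }
        out[idx3(x, y, z, tx, ty)] = val;
      }
  return out;
}

// Warp `vol` into a grid of shape `target`: output voxel p samples the
// input at A %*% p + t (voxel coordinates, 0-based). Outside -> fill.
// [[Rcpp::export]]
NumericVector cpp_affine_warp(NumericVector vol, NumericMatrix A,
                              NumericVector t, IntegerVector target,
                              double fill) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  int tx = target[0], ty = target[1], tz = target[2];
  NumericVector out((size_t)tx * ty * tz);
  out.attr("dim") = IntegerVector::create(tx, ty, tz);
  const double *v = vol.begin();
  for (int z = 0; z < tz; ++z)
    for (int y = 0; y < ty; ++y)
      for (int x = 0; x < tx; ++x) {
        double px = A(0, 0) * x + A(0, 1) * y + A(0, 2) * z + t[0];
        double py = A(1, 0) * x + A(1, 1) * y + A(1, 2) * z + t[1];
        double pz = A(2, 0) * x + A(2, 1) * y + A(2, 2) * z + t[2];
        out[idx3(x, y, z, tx, ty)] = tri_sample(v, nx, ny, nz, px, py, pz, fill);
      }
  return out;
}

// im2col for 3D convolution. Input x: (C, X, Y, Z) column-major with
// channel fastest. Returns (C*k^3) x (Xo*Yo*Zo) matrix, zero padding.
// [[Rcpp::export]]
arma::mat cpp_im2col3(NumericVector x, int C, int X, int Y, int Z, int k,
                      int stride, int pad) {
  int Xo = (X + 2 * pad - k) / stride + 1;
  int Yo = (Y + 2 * pad - k) / stride + 1;
  int Zo = (Z + 2 * pad - k) / stride + 1;
  arma::mat cols(C * k * k * k, (size_t)Xo * Yo * Zo, arma::fill::zeros);
  const double *v = x.begin();
  size_t j = 0;
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox, ++j) {
        double *col = cols.colptr(j);
        for (int kz = 0; kz < k; ++kz) {
          int z = oz * stride + kz - pad;
          if (z < 0 || z >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            int y = oy * stride + ky - pad;
            if (y < 0 || y >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              int xx = ox * stride + kx - pad;
              if (xx < 0 || xx >= X) continue;
              const double *src = v + (size_t)C * (xx + X * (y + (size_t)Y * z));
              double *dst = col + (size_t)C * (kx + k * (ky + k * kz));
              std::copy(src, src + C, dst);
            }
          }
        }
      }
  return cols;
}

// Adjoint of cpp_im2col3: scatter-add columns back into input layout.
// [[Rcpp::export]]
NumericVector cpp_col2im3(arma::mat cols, int C, int X, int Y, int Z, int k,
                          int stride, int pad) {
  int Xo = (X + 2 * pad - k) / stride + 1;
  int Yo = (Y + 2 * pad - k) / stride + 1;
  int Zo = (Z + 2 * pad - k) / stride + 1;
  NumericVector out((size_t)C * X * Y * Z);
  out.attr("dim") = IntegerVector::create(C, X, Y, Z);
  double *v = out.begin();
  size_t j = 0;
  for (int oz = 0; oz < Zo; ++oz)
    for (int oy = 0; oy < Yo; ++oy)
      for (int ox = 0; ox < Xo; ++ox, ++j) {
        const double *col = cols.colptr(j);
        for (int kz = 0; kz < k; ++kz) {
          int z = oz * stride + kz - pad;
          if (z < 0 || z >= Z) continue;
          for (int ky = 0; ky < k; ++ky) {
            int y = oy * stride + ky - pad;
            if (y < 0 || y >= Y) continue;
            for (int kx = 0; kx < k; ++kx) {
              int xx = ox * stride + kx - pad;
              if (xx < 0 || xx >= X) continue;
              double *dst = v + (size_t)C * (xx + X * (y + (size_t)Y * z));
              const double *src = col + (size_t)C * (kx + k * (ky + k * kz));
              for (int c = 0; c < C; ++c) dst[c] += src[c];
            }
          }
        }
      }
  return out;
}
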