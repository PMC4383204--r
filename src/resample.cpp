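#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample a 2-D image (matrix indexed [y, x], 0-based here) at a continuous
// position; bilinear or nearest; outside -> fill.
static inline double sample2d(const NumericMatrix &img, double y, double x,
                              bool nearest, double fill) {
  const int ny = img.nrow(), nx = img.ncol();
  if (nearest) {
    const int iy = (int)std::lround(y), ix = (int)std::lround(x);
    if (iy < 0 || iy >= ny || ix < 0 || ix >= nx) return fill;
    return img(iy, ix);
  }
  const int y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  const double fy = y - y0, fx = x - x0;
  double acc = 0.0;
  for (int dy = 0; dy <= 1; ++dy) {
    for (int dx = 0; dx <= 1; ++dx) {
      const double w = (dy ? fy : 1.0 - fy) * (dx ? fx : 1.0 - fx);
      if (w == 0.0) continue;
      const int iy = y0 + dy, ix = x0 + dx;
      const double v = (iy < 0 || iy >= ny || ix < 0 || ix >= nx) ? fill
                                                                  : img(iy, ix);
      acc += w * v;
    }
  }
  return acc;
}

// Resample `img` under a rigid transform. The transform maps a point q of the
// input onto p = R(theta) (q - c) + c + t of the output, so the output is
// filled by the inverse map: out(p) = img(R(-theta) (p - c - t) + c).
// theta in degrees, counter-clockwise in (y, x) pixel coordinates with y down
// (i.e. standard matrix orientation); center (cy, cx) 0-based pixels.
// [[Rcpp::export]]
NumericMatrix cpp_resample_rigid2d(NumericMatrix img, double dx, double dy,
                                   double theta_deg, double cy, double cx,
                                   bool nearest, double fill) {
  const int ny = img.nrow(), nx = img.ncol();
  NumericMatrix out(ny, nx);
  const double th = theta_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      const double py = iy - cy - dy, px = ix - cx - dx;
      // inverse rotation R(-theta)
      const double qy = ct * py + st * px;
      const double qx = -st * py + ct * px;
      out(iy, ix) = sample2d(img, qy + cy, qx + cx, nearest, fill);
    }
  }
  return out;
}

static inline double sample3d(const double *v, int nz, int ny, int nx,
                              double z, double y, double x, bool nearest,
                              double fill) {
  if (nearest) {
    const int iz = (int)std::lround(z), iy = (int)std::lround(y),
              ix = (int)std::lround(x);
    if (iz < 0 || iz >= nz || iy < 0 || iy >= ny || ix < 0 || ix >= nx)
      return fill;
    return v[iz + (size_t)nz * (iy + (size_t)ny * ix)];
  }
  const int z0 = (int)std::floor(z), y0 = (int)std::floor(y),
            x0 = (int)std::floor(x);
  const double fz = z - z0, fy = y - y0, fx = x - x0;
  double acc = 0.0;
  for (int dz = 0; dz <= 1; ++dz)
    for (int dy = 0; dy <= 1; ++dy)
      for (int dx = 0; dx <= 1; ++dx) {
        const double w = (dz ? fz : 1.0 - fz) * (dy ? fy : 1.0 - fy) *
                         (dx ? fx : 1.0 - fx);
        if (w == 0.0) continue;
        const int iz = z0 + dz, iy = y0 + dy, ix = x0 + dx;
        double val = fill;
        if (iz >= 0 && iz < nz && iy >= 0 && iy < ny && ix >= 0 && ix < nx)
          val = v[iz + (size_t)nz * (iy + (size_t)ny * ix)];
        acc += w * val;
      }
  return acc;
}

// Sample an oblique plane from a 3-D array stored with dim (nz, ny, nx),
// (z, y, x) physical spacing/origin in um. The emitted image has
// image[i, j] = volume value at center + (i - size/2) px f1 + (j - size/2) px f2
// with i, j 0-based.
// [[Rcpp::export]]
NumericMatrix cpp_resample_plane(NumericVector vol, IntegerVector dim,
                                 NumericVector spacing, NumericVector origin,
                                 NumericVector center, NumericVector f1,
                                 NumericVector f2, int size, double pixel_size,
                                 bool nearest, double fill) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericMatrix out(size, size);
  const double *v = REAL(vol);
  const double half = size / 2.0;
  for (int j = 0; j < size; ++j) {
    const double bj = (j - half) * pixel_size;
    for (int i = 0; i < size; ++i) {
      const double bi = (i - half) * pixel_size;
      const double pz = center[0] + bi * f1[0] + bj * f2[0];
      const double py = center[1] + bi * f1[1] + bj * f2[1];
      const double px = center[2] + bi * f1[2] + bj * f2[2];
      const double z = (pz - origin[0]) / spacing[0];
      const double y = (py - origin[1]) / spacing[1];
      const double x = (px - origin[2]) / spacing[2];
      out(i, j) = sample3d(v, nz, ny, nx, z, y, x, nearest, fill);
    }
  }
  return out;
}

// 4-connected component labelling of a binary mask (matrix of 0/1).
// Returns an integer matrix with components numbered 1..n, 0 elsewhere.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components_2d(IntegerMatrix mask) {
  const int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::vector<int> stack;
  int next = 0;
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) {
      if (mask(iy, ix) == 0 || lab(iy, ix) != 0) continue;
      ++next;
      stack.push_back(iy + ny * ix);
      lab(iy, ix) = next;
      while (!stack.empty()) {
        const int cur = stack.back();
        stack.pop_back();
        const int cy = cur % ny, cx = cur / ny;
        const int dys[4] = {-1, 1, 0, 0};
        const int dxs[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int yy = cy + dys[k], xx = cx + dxs[k];
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          if (mask(yy, xx) != 0 && lab(yy, xx) == 0) {
            lab(yy, xx) = next;
            stack.push_back(yy + ny * xx);
          }
        }
      }
    }
  }
  return lab;
}
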