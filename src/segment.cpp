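#include <Rcpp.h>
#include <cmath>
#include <queue>
#include <vector>
using namespace Rcpp;

// Seeded multi-class geodesic labelling on a 6-connected 3-D grid.
//
// The cost of stepping between adjacent voxels u, v separated by physical
// distance h um is
//     w(u, v) = eps * h + ||I(u) - I(v)||_2^2 + beta * (g(u) + g(v)) / 2 * h
// where I is the (possibly multichannel) intensity, g the per-um gradient
// magnitude, eps a small distance term that makes the cost reduce to physical
// distance on constant volumes, and beta the gradient sensitivity. The
// squared intensity difference makes a sharp class boundary far costlier
// than the same contrast spread over many noisy steps. Every
// voxel takes the class of the seed set reachable at minimal accumulated
// cost; equal-cost ties resolve to the lowest class code.
//
// vol: numeric vector, dim (nz, ny, nx, nchan) column-major; seeds: n x 4
// matrix of 0-based (z, y, x, class).
// [[Rcpp::export]]
IntegerVector cpp_segment(NumericVector vol, IntegerVector dim, int nchan,
                          NumericVector spacing, IntegerMatrix seeds,
                          double beta, double eps) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const size_t n = (size_t)nz * ny * nx;
  const double *v = REAL(vol);
  const double hz = spacing[0], hy = spacing[1], hx = spacing[2];

  // per-um gradient magnitude by central differences (one-sided at edges)
  std::vector<double> grad(n, 0.0);
  for (int ix = 0; ix < nx; ++ix)
    for (int iy = 0; iy < ny; ++iy)
      for (int iz = 0; iz < nz; ++iz) {
        double acc = 0.0;
        for (int c = 0; c < nchan; ++c) {
          const size_t off = (size_t)c * n;
          const size_t idx = iz + (size_t)nz * (iy + (size_t)ny * ix);
          const int zm = iz > 0 ? iz - 1 : iz, zp = iz < nz - 1 ? iz + 1 : iz;
          const int ym = iy > 0 ? iy - 1 : iy, yp = iy < ny - 1 ? iy + 1 : iy;
          const int xm = ix > 0 ? ix - 1 : ix, xp = ix < nx - 1 ? ix + 1 : ix;
          double d;
          if (zp > zm) {
            d = (v[off + zp + (size_t)nz * (iy + (size_t)ny * ix)] -
                 v[off + zm + (size_t)nz * (iy + (size_t)ny * ix)]) /
                ((zp - zm) * hz);
            acc += d * d;
          }
          if (yp > ym) {
            d = (v[off + iz + (size_t)nz * (yp + (size_t)ny * ix)] -
                 v[off + iz + (size_t)nz * (ym + (size_t)ny * ix)]) /
                ((yp - ym) * hy);
            acc += d * d;
          }
          if (xp > xm) {
            d = (v[off + iz + (size_t)nz * (iy + (size_t)ny * xp)] -
                 v[off + iz + (size_t)nz * (iy + (size_t)ny * xm)]) /
                ((xp - xm) * hx);
            acc += d * d;
          }
          (void)idx;
        }
        grad[iz + (size_t)nz * (iy + (size_t)ny * ix)] = std::sqrt(acc);
      }

  std::vector<double> dist(n, R_PosInf);
  std::vector<int> lab(n, -1);
  std::vector<char> done(n, 0);

  struct Node {
    double d;
    int cls;
    size_t idx;
  };
  struct Cmp {
    bool operator()(const Node &a, const Node &b) const {
      if (a.d != b.d) return a.d > b.d;
      if (a.cls != b.cls) return a.cls > b.cls;
      return a.idx > b.idx;
    }
  };
  std::priority_queue<Node, std::vector<Node>, Cmp> pq;

  for (int s = 0; s < seeds.nrow(); ++s) {
    const size_t idx =
        seeds(s, 0) + (size_t)nz * (seeds(s, 1) + (size_t)ny * seeds(s, 2));
    const int cls = seeds(s, 3);
    if (0.0 < dist[idx] || (dist[idx] == 0.0 && cls < lab[idx])) {
      dist[idx] = 0.0;
      lab[idx] = cls;
      pq.push({0.0, cls, idx});
    }
  }

  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  const double hs[6] = {hz, hz, hy, hy, hx, hx};

  while (!pq.empty()) {
    const Node nd = pq.top();
    pq.pop();
    if (done[nd.idx] || nd.d > dist[nd.idx] ||
        (nd.d == dist[nd.idx] && nd.cls > lab[nd.idx]))
      continue;
    done[nd.idx] = 1;
    const int iz = (int)(nd.idx % nz);
    const int iy = (int)((nd.idx / nz) % ny);
    const int ix = (int)(nd.idx / ((size_t)nz * ny));
    for (int k = 0; k < 6; ++k) {
      const int z = iz + dz[k], y = iy + dy[k], x = ix + dx[k];
      if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
      const size_t j = z + (size_t)nz * (y + (size_t)ny * x);
      if (done[j]) continue;
      double di = 0.0;
      for (int c = 0; c < nchan; ++c) {
        const double d = v[(size_t)c * n + nd.idx] - v[(size_t)c * n + j];
        di += d * d;
      }
      const double w = eps * hs[k] + di +
                       beta * 0.5 * (grad[nd.idx] + grad[j]) * hs[k];
      const double cand = nd.d + w;
      if (cand < dist[j] || (cand == dist[j] && nd.cls < lab[j])) {
        dist[j] = cand;
        lab[j] = nd.cls;
        pq.push({cand, nd.cls, j});
      }
    }
  }

  IntegerVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; ++i) out[i] = lab[i];
  return out;
}
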