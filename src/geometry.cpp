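// Voxelisation of tube-shaped bundles and 26-connectivity labeling.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Occupancy of a tube of given radius around a densely sampled centerline.
// pts/tangents are N x 3 in world mm; voxel centre of index i is i * h.
// Returns the mask, the unit tangent of the nearest centerline sample for
// each inside voxel, and the nearest sample index (1-based, 0 outside).
// [[Rcpp::export]]
List cpp_tube_occupancy(IntegerVector dim, NumericVector voxsize,
                        NumericMatrix pts, NumericMatrix tangents,
                        double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double hx = voxsize[0], hy = voxsize[1], hz = voxsize[2];
  const int N = pts.nrow();
  const size_t nvox = (size_t)nx * ny * nz;

  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < N; ++i)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], pts(i, c));
      hi[c] = std::max(hi[c], pts(i, c));
    }
  const int x0 = std::max(0, (int)std::floor((lo[0] - radius) / hx));
  const int y0 = std::max(0, (int)std::floor((lo[1] - radius) / hy));
  const int z0 = std::max(0, (int)std::floor((lo[2] - radius) / hz));
  const int x1 = std::min(nx - 1, (int)std::ceil((hi[0] + radius) / hx));
  const int y1 = std::min(ny - 1, (int)std::ceil((hi[1] + radius) / hy));
  const int z1 = std::min(nz - 1, (int)std::ceil((hi[2] + radius) / hz));

  LogicalVector mask(nvox);
  NumericVector tang(3 * nvox);
  IntegerVector nearest(nvox);
  const double r2 = radius * radius;

  for (int z = z0; z <= z1; ++z)
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        const double px = x * hx, py = y * hy, pz = z * hz;
        double best = R_PosInf;
        int bi = -1;
        for (int i = 0; i < N; ++i) {
          const double dx = px - pts(i, 0), dy = py - pts(i, 1),
                       dz = pz - pts(i, 2);
          const double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 < best) {
            best = d2;
            bi = i;
          }
        }
        if (best <= r2) {
          const size_t li = (size_t)x + nx * ((size_t)y + (size_t)ny * z);
          mask[li] = true;
          tang[3 * li + 0] = tangents(bi, 0);
          tang[3 * li + 1] = tangents(bi, 1);
          tang[3 * li + 2] = tangents(bi, 2);
          nearest[li] = bi + 1;
        }
      }
  tang.attr("dim") = IntegerVector::create(3, nx, ny, nz);
  return List::create(_["mask"] = mask, _["tangent"] = tang,
                      _["nearest"] = nearest);
}

// Connected-component labeling of a binary volume, 26-connectivity.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t nvox = (size_t)nx * ny * nz;
  IntegerVector lab(nvox);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t s = 0; s < nvox; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const size_t c = stack.back();
      stack.pop_back();
      const int x = c % nx, y = (c / nx) % ny, z = c / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            const int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz)
              continue;
            const size_t n = (size_t)X + nx * ((size_t)Y + (size_t)ny * Z);
            if (mask[n] && !lab[n]) {
              lab[n] = next;
              stack.push_back(n);
            }
          }
    }
  }
  return lab;
}
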