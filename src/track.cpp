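// Probabilistic streamline propagation through a field of per-voxel
// orientation posterior samples, with seed / waypoint / termination /
// exclusion mask semantics and visitation counting.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include "rng.h"

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  double hx, hy, hz;
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && y >= 0 && z >= 0 && x < nx && y < ny && z < nz;
  }
  inline int lin(int x, int y, int z) const { return x + nx * (y + ny * z); }
  // voxel centre of index i lies at i * h (world mm)
  inline int ix(double p, double h) const {
    return (int)std::lround(p / h);
  }
};

enum Reason { EXITED = 0, CURVATURE = 1, TERMINATION = 2, MAXSTEPS = 3,
              EXCLUDED = 4 };

const char *reason_str(int r) {
  switch (r) {
    case EXITED: return "exited";
    case CURVATURE: return "curvature";
    case TERMINATION: return "termination";
    case MAXSTEPS: return "max_steps";
    case EXCLUDED: return "excluded";
  }
  return "?";
}

struct Field {
  const int *index;      // nvox, -1 = outside brain mask, else sample row
  const double *V;       // 3 x K x nfit
  int K;
  inline void draw(int row, SplitMix &rng, double *v) const {
    int k = rng.rint(K);
    const double *src = V + 3 * ((size_t)K * row + k);
    v[0] = src[0];
    v[1] = src[1];
    v[2] = src[2];
  }
};

// Propagate one side; returns termination reason. Records newly entered
// voxels into `visited` and ORs waypoint bits into `bits`.
int propagate_side(const Grid &gr, const Field &fd, const int *wp,
                   const int *term, const int *excl, double px, double py,
                   double pz, double dx, double dy, double dz, double curv,
                   double step, int max_steps, SplitMix &rng,
                   std::vector<int> &visited, unsigned int &bits,
                   std::vector<double> *poly) {
  double pdx = dx, pdy = dy, pdz = dz;
  int last = -1;
  for (int s = 0; s < max_steps; ++s) {
    double vx, vy, vz;
    if (s == 0) {
      vx = pdx; vy = pdy; vz = pdz; // first direction: no curvature test
    } else {
      int cx = gr.ix(px, gr.hx), cy = gr.ix(py, gr.hy), cz = gr.ix(pz, gr.hz);
      int row = fd.index[gr.lin(cx, cy, cz)];
      if (row < 0) return EXITED;
      double v[3];
      fd.draw(row, rng, v);
      double dot = v[0] * pdx + v[1] * pdy + v[2] * pdz;
      if (dot < 0) { v[0] = -v[0]; v[1] = -v[1]; v[2] = -v[2]; dot = -dot; }
      if (dot < curv) return CURVATURE;
      vx = v[0]; vy = v[1]; vz = v[2];
    }
    px += step * vx;
    py += step * vy;
    pz += step * vz;
    int x = gr.ix(px, gr.hx), y = gr.ix(py, gr.hy), z = gr.ix(pz, gr.hz);
    if (!gr.inside(x, y, z)) return EXITED;
    int li = gr.lin(x, y, z);
    if (fd.index[li] < 0 && !(term && term[li])) return EXITED;
    if (poly) {
      poly->push_back(px);
      poly->push_back(py);
      poly->push_back(pz);
    }
    if (li != last) {
      visited.push_back(li);
      if (wp) bits |= (unsigned int)wp[li];
      last = li;
    }
    if (term && term[li]) return TERMINATION;
    if (excl && excl[li]) return EXCLUDED;
    pdx = vx; pdy = vy; pdz = vz;
  }
  return MAXSTEPS;
}

} // namespace

// [[Rcpp::export]]
List cpp_track(IntegerVector dim, NumericVector voxsize, IntegerVector index,
               NumericVector V, int K, IntegerVector seed_vox,
               IntegerVector waypoint_bits, IntegerVector termination,
               IntegerVector exclusion, int n_waypoints, int nsamples,
               double curv, double step, int max_steps, double seed) {
  Grid gr{dim[0], dim[1], dim[2], voxsize[0], voxsize[1], voxsize[2]};
  Field fd{index.begin(), V.begin(), K};
  const int *wp = waypoint_bits.size() ? waypoint_bits.begin() : nullptr;
  const int *term = termination.size() ? termination.begin() : nullptr;
  const int *excl = exclusion.size() ? exclusion.begin() : nullptr;
  const unsigned int all_bits =
      n_waypoints >= 32 ? 0xFFFFFFFFu : ((1u << n_waypoints) - 1u);

  IntegerVector counts(index.size());
  long long n_retained = 0;
  const long long n_launched = (long long)seed_vox.size() * nsamples;
  std::vector<int> visited;
  visited.reserve(4096);

  for (int sv = 0; sv < seed_vox.size(); ++sv) {
    const int li0 = seed_vox[sv];
    const int z0 = li0 / (gr.nx * gr.ny);
    const int y0 = (li0 / gr.nx) % gr.ny;
    const int x0 = li0 % gr.nx;
    const double px = x0 * gr.hx, py = y0 * gr.hy, pz = z0 * gr.hz;
    const int row0 = fd.index[li0];

    for (int m = 0; m < nsamples; ++m) {
      SplitMix rng(mix_seed(mix_seed((uint64_t)seed, (uint64_t)li0),
                            (uint64_t)m));
      visited.clear();
      unsigned int bits = 0;
      bool excluded = false;
      visited.push_back(li0);
      if (wp) bits |= (unsigned int)wp[li0];
      bool at_term = term && term[li0];
      if (excl && excl[li0]) excluded = true;

      if (!excluded && !at_term && row0 >= 0) {
        double d0[3];
        fd.draw(row0, rng, d0);
        int r1 = propagate_side(gr, fd, wp, term, excl, px, py, pz, d0[0],
                                d0[1], d0[2], curv, step, max_steps, rng,
                                visited, bits, nullptr);
        if (r1 == EXCLUDED) excluded = true;
        if (!excluded) {
          int r2 = propagate_side(gr, fd, wp, term, excl, px, py, pz, -d0[0],
                                  -d0[1], -d0[2], curv, step, max_steps, rng,
                                  visited, bits, nullptr);
          if (r2 == EXCLUDED) excluded = true;
        }
      }
      if (excluded) continue;
      if (bits != all_bits) continue;
      std::sort(visited.begin(), visited.end());
      visited.erase(std::unique(visited.begin(), visited.end()),
                    visited.end());
      for (int li : visited) ++counts[li];
      ++n_retained;
    }
  }
  return List::create(_["counts"] = counts,
                      _["n_launched"] = (double)n_launched,
                      _["n_retained"] = (double)n_retained);
}

// [[Rcpp::export]]
List cpp_propagate_one(IntegerVector dim, NumericVector voxsize,
                       IntegerVector index, NumericVector V, int K,
                       IntegerVector termination, NumericVector start,
                       double curv, double step, int max_steps, double seed) {
  Grid gr{dim[0], dim[1], dim[2], voxsize[0], voxsize[1], voxsize[2]};
  Field fd{index.begin(), V.begin(), K};
  const int *term = termination.size() ? termination.begin() : nullptr;

  SplitMix rng(mix_seed((uint64_t)seed, 0x7261CEULL));
  std::vector<int> visited;
  unsigned int bits = 0;
  std::vector<double> poly;
  poly.push_back(start[0]);
  poly.push_back(start[1]);
  poly.push_back(start[2]);

  int x = gr.ix(start[0], gr.hx), y = gr.ix(start[1], gr.hy),
      z = gr.ix(start[2], gr.hz);
  int row = fd.index[gr.lin(x, y, z)];
  int reason;
  if (row < 0) {
    reason = EXITED;
  } else {
    double d0[3];
    fd.draw(row, rng, d0);
    reason = propagate_side(gr, fd, nullptr, term, nullptr, start[0],
                            start[1], start[2], d0[0], d0[1], d0[2], curv,
                            step, max_steps, rng, visited, bits, &poly);
  }
  NumericMatrix pts(poly.size() / 3, 3);
  for (size_t i = 0; i < poly.size() / 3; ++i) {
    pts(i, 0) = poly[3 * i];
    pts(i, 1) = poly[3 * i + 1];
    pts(i, 2) = poly[3 * i + 2];
  }
  return List::create(_["points"] = pts,
                      _["reason"] = std::string(reason_str(reason)));
}
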