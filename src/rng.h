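#ifndef TRACTDISSECT_RNG_H
#define TRACTDISSECT_RNG_H

#include <cstdint>
#include <cmath>

// Small counter-based generator (splitmix64). Every streamline / voxel owns
// an independent stream derived by hashing (seed, ids...), so results do not
// depend on iteration order and are reproducible across platforms.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  inline uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on (0,1), never exactly 0 or 1
  inline double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rnorm() {
    double u1 = runif(), u2 = runif();
    return std::sqrt(-2.0 * std::log(u1)) *
           std::cos(6.283185307179586476925287 * u2);
  }
  inline int rint(int n) { return static_cast<int>(next() % (uint64_t)n); }
};

inline uint64_t mix_seed(uint64_t a, uint64_t b) {
  uint64_t z = a * 0x9E3779B97F4A7C15ULL + b + 0x2545F4914F6CDD1DULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

#endif
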