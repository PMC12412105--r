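#ifndef CAPSORT_RNG_H
#define CAPSORT_RNG_H

#include <cstdint>
#include <cmath>

// xoshiro256+ with splitmix64 seeding: fast, reproducible across platforms,
// independent of R's global RNG stream (seeds are always passed explicitly).
struct Xoshiro {
  uint64_t s[4];

  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double runif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // uniform in [-1, 1)
  inline double runif_sym() {
    return 2.0 * runif() - 1.0;
  }

  inline int rint(int n) {  // uniform in {0, ..., n-1}
    return (int)(runif() * n);
  }

  // standard normal via Box-Muller (no cache; used in bulk loops)
  inline double rnorm() {
    double u1 = runif(), u2 = runif();
    if (u1 < 1e-300) u1 = 1e-300;
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

#endif
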