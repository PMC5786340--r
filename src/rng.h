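#ifndef COOPGATE_RNG_H
#define COOPGATE_RNG_H

#include <cstdint>
#include <cmath>

// Small self-contained counter-seeded RNG (xoshiro256++, splitmix64 seeding).
// One independent stream per cluster / release unit: stream k of master seed s
// is seeded from splitmix64 initialised at s*2^32 + k, so streams are
// decorrelated and every simulation is reproducible from (seed, stream id).
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t master, uint64_t stream) {
    uint64_t x = master * 0x100000000ULL + stream + 1ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  inline double unif() {
    return (next() >> 11) * 0x1.0p-53;
  }

  // binomial via geometric waiting times; work is O(n p + 1), exact.
  inline int binom(int n, double p) {
    if (n <= 0 || p <= 0.0) return 0;
    if (p >= 1.0) return n;
    double logq = std::log1p(-p);
    int count = 0;
    double sum = 0.0;
    for (;;) {
      double u = unif();
      if (u <= 0.0) u = 0x1.0p-53;
      sum += std::floor(std::log(u) / logq) + 1.0;
      if (sum > n) break;
      ++count;
    }
    return count;
  }
};

#endif
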