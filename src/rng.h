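#ifndef PHOTOTHERM_RNG_H
#define PHOTOTHERM_RNG_H

#include <cstdint>

// xoshiro256+ seeded through splitmix64: a small, fast, well-tested stream
// generator that is bit-reproducible across platforms and independent of
// R's global RNG state. One instance per traced run, one user seed.
struct Xoshiro256 {
  uint64_t s[4];

  explicit Xoshiro256(uint64_t seed) {
    // splitmix64 expansion of the single seed into the 256-bit state
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

  inline uint64_t next_u64() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on (0, 1]: never returns 0, so -log(xi) is always finite
  inline double next_unif(void) {
    return 1.0 - (next_u64() >> 11) * 0x1.0p-53;
  }
};

#endif
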