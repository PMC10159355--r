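#pragma once
#include <cstdint>

// xoshiro256++ with splitmix64 seeding. One independent instance per stochastic
// process category so that adding draws to one process never perturbs another.
struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed_from(uint64_t &sm) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(sm);
  }

  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }

  uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }

  // Uniform on (0,1]: p = 0 can never trigger, p = 1 always triggers.
  double unif_oc() { return 1.0 - ((next() >> 11) * 0x1.0p-53); }

  // Uniform integer in 0..n-1 from a single draw.
  int pick(int n) {
    int k = (int)(unif_oc() * n);  // u in (0,1] -> u*n in (0,n]
    if (k >= n) k = n - 1;         // u == 1 lands exactly on n
    return k;
  }
};

// Stream ids shared between C++ and R (see R/rng.R).
enum StreamId {
  STR_MOVEMENT = 0,
  STR_DIVISION = 1,
  STR_INTRAVASATION = 2,
  STR_ZONE_EXIT = 3,
  STR_PHENOTYPE = 4,
  STR_VESSEL = 5,
  STR_SCHEDULER = 6,
  N_STREAMS = 7
};

struct Streams {
  Xoshiro s[N_STREAMS];
  void seed_all(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < N_STREAMS; ++i) s[i].seed_from(sm);
  }
};
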