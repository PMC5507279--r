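#ifndef RPSIM_RNG_H
#define RPSIM_RNG_H

#include <cstdint>
#include <cmath>

// Private, seedable xoshiro256++ stream. The simulator does not touch R's RNG:
// every stochastic draw of a run (placement, lifetimes, shuffles, moves,
// reaction tests, mutations) consumes from one instance of this generator in a
// fixed documented order, so a (config, seed) pair determines a run exactly.
namespace rpsim {

inline std::uint64_t splitmix64(std::uint64_t &x) {
  std::uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

struct Rng {
  std::uint64_t s[4];

  void seed(std::uint64_t sd) {
    std::uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static std::uint64_t rotl(std::uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  std::uint64_t next() {
    std::uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    std::uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform on [0, 1), 53-bit resolution
  double unif() { return (next() >> 11) * 0x1.0p-53; }

  // uniform on (0, 1]
  double unif_oc() { return 1.0 - unif(); }

  // Exp(k) waiting time; rate 0 means the event never fires
  double rexp(double k) {
    if (k <= 0.0) return INFINITY;
    return -std::log(unif_oc()) / k;
  }

  // unbiased-enough bounded integer in [0, n) via 128-bit multiply-high
  std::uint32_t bounded(std::uint32_t n) {
    return (std::uint32_t)(((__uint128_t)next() * n) >> 64);
  }

  // one standard-normal pair by Box-Muller (fixed two-uniform consumption)
  void gauss_pair(double &g1, double &g2) {
    double u1 = unif_oc();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    g1 = r * std::cos(th);
    g2 = r * std::sin(th);
  }
};

} // namespace rpsim

#endif
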