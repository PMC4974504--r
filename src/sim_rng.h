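#ifndef FRETDYN_SIM_RNG_H
#define FRETDYN_SIM_RNG_H

#include <cstdint>
#include <cmath>
#include <random>

// Self-contained RNG for the photon simulator: mt19937_64 (bit-exact by
// the C++ standard) with hand-written transforms, so streams are
// reproducible across platforms and standard libraries.
struct SimRng {
  std::mt19937_64 eng;
  bool have_spare = false;
  double spare = 0.0;

  explicit SimRng(std::uint64_t seed) : eng(seed) {}

  double runif() {
    // 53-bit mantissa uniform in (0,1)
    double u = ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    return u;
  }

  double rnorm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * runif() - 1.0;
      v = 2.0 * runif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    have_spare = true;
    return u * f;
  }

  double rexp(double rate) { return -std::log(runif()) / rate; }

  // Poisson by inversion; intended for small means (< ~15)
  int rpois_small(double lambda) {
    double L = std::exp(-lambda), p = runif(), cum = L, term = L;
    int k = 0;
    while (p > cum) {
      ++k;
      term *= lambda / k;
      cum += term;
      if (k > 1000) break;
    }
    return k;
  }
};

#endif
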