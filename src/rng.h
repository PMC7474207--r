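#ifndef GOPULL_RNG_H
#define GOPULL_RNG_H

#include <cstdint>
#include <cmath>

// Small self-contained RNG (xoshiro256**, seeded through splitmix64) so that
// trajectories are bit-reproducible for a given integer seed independently of
// the C++ standard library's distribution implementations.
class Rng {
 public:
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed into the 256-bit state
    uint64_t z = seed;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s_[i] = t ^ (t >> 31);
    }
    z_ = &zig();  // resolve the static-init guard once per trajectory
  }

  double unif() {  // uniform in (0, 1)
    return (next() >> 11) * 0x1.0p-53 + 0x1.0p-54;
  }

  // standard normal via a 128-layer ziggurat (tail by Marsaglia's method);
  // several times faster than the polar method, which matters because the
  // Brownian integrator draws 3N normals per step
  double norm() {
    const Zig& z = *z_;
    for (;;) {
      uint64_t b = next();
      int i = (int)(b & 127);
      double u = ((int64_t)(b >> 11) * 0x1.0p-52) - 1.0;  // [-1, 1)
      double x = u * z.x[i];
      if (std::fabs(u) < z.ratio[i]) return x;
      if (i == 0) {  // tail beyond R
        double xx, yy;
        do {
          xx = -std::log(unif()) / z.x[1];
          yy = -std::log(unif());
        } while (yy + yy < xx * xx);
        return u < 0 ? -(z.x[1] + xx) : z.x[1] + xx;
      }
      // wedge: accept with prob (f(x)-f(X_i)) / (f(X_{i+1})-f(X_i))
      double f0 = std::exp(-0.5 * (z.x[i] * z.x[i] - x * x));
      double f1 = std::exp(-0.5 * (z.x[i + 1] * z.x[i + 1] - x * x));
      if (f0 + unif() * (f1 - f0) < 1.0) return x;
    }
  }

 private:
  // ziggurat tables (Doornik-style layout, 128 blocks,
  // R = 3.442619855899, V = 9.91256303526217e-3)
  struct Zig {
    double x[129];
    double ratio[128];
    Zig() {
      const double R = 3.442619855899, V = 9.91256303526217e-3;
      x[0] = V / std::exp(-0.5 * R * R);
      x[1] = R;
      x[128] = 0.0;
      for (int i = 2; i < 128; ++i) {
        double prev = x[i - 1];
        x[i] = std::sqrt(-2.0 *
                         std::log(V / prev + std::exp(-0.5 * prev * prev)));
      }
      for (int i = 0; i < 128; ++i) ratio[i] = x[i + 1] / x[i];
    }
  };

  uint64_t s_[4];
  const Zig* z_;

  static const Zig& zig() {
    static const Zig z;  // initialized once at first use
    return z;
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    uint64_t result = rotl(s_[1] * 5, 7) * 9;
    uint64_t t = s_[1] << 17;
    s_[2] ^= s_[0];
    s_[3] ^= s_[1];
    s_[1] ^= s_[2];
    s_[0] ^= s_[3];
    s_[2] ^= t;
    s_[3] = rotl(s_[3], 45);
    return result;
  }
};

#endif
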