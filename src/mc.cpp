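#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Self-contained counter-free RNG (xoshiro256++) so that per-node streams are
// reproducible across platforms and independent of R's global RNG state.

static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro256pp {
  uint64_t s[4];
  explicit Xoshiro256pp(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(x);
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in [0, 1)
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Unpolarized Fresnel reflectance for a photon hitting the surface from the
// tissue side (n1 = tissue, n2 = above) with incidence cosine ci in (0, 1].
static inline double fresnel_reflectance(double ci, double n1, double n2,
                                         double &sin_i) {
  if (ci > 1.0) ci = 1.0;
  sin_i = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double sin_t = n1 / n2 * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double ct = std::sqrt(1.0 - sin_t * sin_t);
  if (sin_i < 1e-9) {  // normal incidence limit
    double r0 = (n1 - n2) / (n1 + n2);
    return r0 * r0;
  }
  double rs = (n1 * ci - n2 * ct) / (n1 * ci + n2 * ct);
  double rp = (n1 * ct - n2 * ci) / (n1 * ct + n2 * ci);
  return 0.5 * (rs * rs + rp * rp);
}

// Single-node reflectance estimate for a semi-infinite homogeneous medium and
// a two-fiber surface probe. Implicit-capture weighting, Henyey-Greenstein
// scattering, Russian roulette below weight_threshold, and an unbiased
// step-count roulette beyond max_steps so that conservative (mua = 0) media
// terminate without truncation bias. Returns c(estimate, standard_error).
// [[Rcpp::export]]
NumericVector mc_reflectance_cpp(double mua, double musp, double g,
                                 double src_r, double det_r, double sep,
                                 double na, double n_tissue, double n_above,
                                 int n_photons, double weight_threshold,
                                 double roulette_survival, double seed,
                                 double stream, double max_steps) {
  if (mua < 0 || musp < 0) stop("optical coefficients must be non-negative");
  if (n_photons < 1) stop("n_photons must be >= 1");
  if (g <= -1 || g >= 1) stop("anisotropy g must lie in (-1, 1)");

  // no scattering: collimated launch never turns back; nothing is detected
  if (musp == 0.0) return NumericVector::create(0.0, 0.0);

  const double mus = musp / (1.0 - g);
  const double mut = mua + mus;
  const double albedo = mus / mut;
  const bool full_surface = !R_finite(det_r);
  const bool na_cut = na < n_above;  // na >= n_above accepts every exit angle
  const double det_r2 = full_surface ? 0.0 : det_r * det_r;
  // Conservative medium, matched boundary, full-surface detection, no
  // angular cut: any live photon escapes and is detected with probability 1
  // (the depth random walk is recurrent), so its remaining weight can be
  // scored analytically at termination. This removes the heavy-tailed
  // long-walk variance from the energy-conservation regime.
  const bool analytic_tail = (mua == 0.0) && full_surface && !na_cut &&
    (n_tissue == n_above);

  uint64_t x = (uint64_t)seed;
  x ^= 0x9E3779B97F4A7C15ULL * ((uint64_t)stream + 1ULL);
  Xoshiro256pp rng(splitmix64_next(x));

  double sum_w = 0.0, sum_w2 = 0.0;

  for (int ip = 0; ip < n_photons; ++ip) {
    // launch: uniform over the source fiber face, directed into the tissue
    double rr = src_r * std::sqrt(rng.unif());
    double phi = 2.0 * M_PI * rng.unif();
    double px = rr * std::cos(phi), py = rr * std::sin(phi), pz = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0;
    double detected = 0.0;
    long steps = 0;
    bool alive = true;

    while (alive) {
      double s = -std::log(1.0 - rng.unif()) / mut;

      // surface interactions, possibly several within one free path
      while (uz < 0.0 && pz + uz * s < 0.0) {
        double db = -pz / uz;
        px += ux * db;
        py += uy * db;
        pz = 0.0;
        s -= db;
        double ci = -uz;
        double sin_i;
        double R = fresnel_reflectance(ci, n_tissue, n_above, sin_i);
        if (R < 1.0) {
          double wt = w * (1.0 - R);
          bool accepted = full_surface ||
            ((px - sep) * (px - sep) + py * py <= det_r2);
          if (accepted && na_cut) accepted = (n_tissue * sin_i <= na);
          if (accepted) detected += wt;
          w *= R;
        }
        uz = -uz;
        if (w <= 0.0) { alive = false; break; }
      }
      if (!alive) break;

      px += ux * s;
      py += uy * s;
      pz += uz * s;

      w *= albedo;  // implicit capture: deposit mua/mut of the weight
      ++steps;

      if (w < weight_threshold) {
        if (rng.unif() < roulette_survival) w /= roulette_survival;
        else break;
      }
      if (steps > (long)max_steps) {
        if (analytic_tail) { detected += w; break; }
        // otherwise terminate long walks by an unbiased roulette
        const double p_keep = 0.95;
        if (rng.unif() < p_keep) w /= p_keep;
        else break;
      }

      // Henyey-Greenstein deflection
      double ct;
      if (std::fabs(g) < 1e-6) {
        ct = 2.0 * rng.unif() - 1.0;
      } else {
        double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * rng.unif());
        ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
        if (ct > 1.0) ct = 1.0;
        if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      // uniform azimuth by rejection (no trig calls)
      double a, b, r2;
      do {
        a = 2.0 * rng.unif() - 1.0;
        b = 2.0 * rng.unif() - 1.0;
        r2 = a * a + b * b;
      } while (r2 > 1.0 || r2 == 0.0);
      double inv = 1.0 / std::sqrt(r2);
      double cph = a * inv, sph = b * inv;

      if (std::fabs(uz) > 0.99999) {
        ux = st * cph;
        uy = st * sph;
        uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cph - uy * sph) / den + ux * ct;
        double nuy = st * (uy * uz * cph + ux * sph) / den + uy * ct;
        double nuz = -st * cph * den + uz * ct;
        ux = nux;
        uy = nuy;
        uz = nuz;
      }
    }

    sum_w += detected;
    sum_w2 += detected * detected;
  }

  double n = (double)n_photons;
  double mean = sum_w / n;
  double var = (sum_w2 - n * mean * mean) / std::max(1.0, n - 1.0);
  if (var < 0) var = 0;
  double se = std::sqrt(var / n);
  return NumericVector::create(mean, se);
}
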