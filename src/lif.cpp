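#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Counter-free splitmix64: used both to expand seeds and to decorrelate
// per-neuron streams.
static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ with Box-Muller normals; self-contained so that spike trains
// are bit-reproducible across platforms for a given seed.
struct Rng {
  uint64_t s[4];
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * 0x1.0p-53;
  }
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    const double u = unif();
    const double v = unif();
    const double m = std::sqrt(-2.0 * std::log(u));
    spare = m * std::sin(2.0 * M_PI * v);
    have_spare = true;
    return m * std::cos(2.0 * M_PI * v);
  }
};

// Euler-Maruyama integration of n independent leaky integrate-and-fire
// neurons sharing a deterministic drive trace but with independent white
// noise, discretized as
//   V <- V + (dt/tau_m) (drive - V) + sigma sqrt(dt/tau_m) N(0,1),
// whose stationary subthreshold variance is sigma^2/2, matching the
// Siegert-rate convention used by the analytic module. Spikes are
// registered at the end of the crossing step; V is clamped at v_r and
// input ignored during the refractory period.
// [[Rcpp::export]]
List lif_population_cpp(const int n_neurons,
                        const NumericVector& drive,
                        const double dt,
                        const double tau_m,
                        const double tau_r,
                        const double v_th,
                        const double v_r,
                        const double sigma,
                        const double seed,
                        const bool return_spikes) {
  const R_xlen_t n_steps = drive.size();
  if (n_neurons < 1) stop("n_neurons must be >= 1");
  if (dt <= 0) stop("dt must be positive");
  const int refr_steps = (int)std::floor(tau_r / dt + 0.5);
  const double leak = dt / tau_m;
  const double noise_amp = sigma * std::sqrt(dt / tau_m);
  // Broadie-Glasserman-Kou continuity correction for the first-passage
  // bias of the Euler scheme: crossings missed between samples are
  // compensated by moving the detection boundary closer by
  // |zeta(1/2)|/sqrt(2 pi) * (diffusion coeff) * sqrt(dt).
  const double th_eff = v_th - 0.5826 * sigma * std::sqrt(dt / tau_m);

  IntegerVector counts(n_steps);
  IntegerVector spikes_per_neuron(n_neurons);
  std::vector<std::vector<double>> spike_times;
  if (return_spikes) spike_times.resize(n_neurons);

  const uint64_t base = (uint64_t)(int64_t)seed;
  for (int i = 0; i < n_neurons; ++i) {
    uint64_t sx = base;
    (void)splitmix64(sx);
    sx ^= (uint64_t)(i + 1) * 0x9E3779B97F4A7C15ULL;
    Rng rng(splitmix64(sx));
    // random initial phase: uniform on [v_r, v_th) desynchronizes the
    // population in the noiseless case
    double V = v_r + (v_th - v_r) * rng.unif();
    int refr = 0;
    for (R_xlen_t t = 0; t < n_steps; ++t) {
      if (refr > 0) { --refr; continue; }
      V += leak * (drive[t] - V);
      if (noise_amp > 0) V += noise_amp * rng.norm();
      if (V >= th_eff) {
        counts[t] += 1;
        spikes_per_neuron[i] += 1;
        if (return_spikes) spike_times[i].push_back((double)(t + 1) * dt);
        V = v_r;
        refr = refr_steps;
      }
    }
    if (!std::isfinite(V))
      stop("membrane potential diverged (NaN/Inf); reduce dt");
  }

  List out = List::create(_["counts"] = counts,
                          _["spikes_per_neuron"] = spikes_per_neuron);
  if (return_spikes) {
    List st(n_neurons);
    for (int i = 0; i < n_neurons; ++i) st[i] = wrap(spike_times[i]);
    out["spike_times"] = st;
  }
  return out;
}
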