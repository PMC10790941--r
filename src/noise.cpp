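#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Fast synthesis kernel for multi-channel 1/f ("pink") background noise.
//
// Uses a dedicated xoshiro256++ stream (seeded from an R integer) with a
// Box-Muller transform, then shapes the spectrum with the Kasdin AR
// approximation to a 1/f^beta process: white noise driven through the
// recursion with coefficients a_k = (k - 1 - beta/2) * a_{k-1} / k.
// Per-channel output is variance-normalized only approximately (the AR gain
// is absorbed by the caller's amplitude scaling, which is calibrated once).

static inline uint64_t rotl(const uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the state
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    for (int i = 0; i < 4; ++i) {
      z += 0x9e3779b97f4a7c15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
      t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
      s[i] = t ^ (t >> 31);
    }
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  // standard normal, Box-Muller with both values used
  bool have_spare = false;
  double spare = 0.0;
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// [[Rcpp::export(rng = false)]]
Rcpp::NumericMatrix pink_noise_cpp(int n, int n_channels, double exponent,
                                   double seed) {
  if (n < 1 || n_channels < 1)
    Rcpp::stop("`n` and `n_channels` must be positive");
  const int order = 5;  // AR order; accurate 1/f shape over the EEG band
  double a1, a2, a3, a4, a5;
  {
    std::vector<double> a(order + 1);
    a[0] = 1.0;
    for (int k = 1; k <= order; ++k)
      a[k] = (k - 1.0 - exponent / 2.0) * a[k - 1] / k;
    a1 = a[1]; a2 = a[2]; a3 = a[3]; a4 = a[4]; a5 = a[5];
  }

  Rcpp::NumericMatrix out(n, n_channels);
  Xoshiro rng(static_cast<uint64_t>(seed));

  for (int ch = 0; ch < n_channels; ++ch) {
    double h1 = 0, h2 = 0, h3 = 0, h4 = 0, h5 = 0;
    double* col = &out(0, ch);
    // warm-up so the AR state forgets the zero initial condition
    const int warm = 2000;
    for (int i = -warm; i < n; ++i) {
      double x = rng.norm() - a1 * h1 - a2 * h2 - a3 * h3 - a4 * h4 - a5 * h5;
      h5 = h4; h4 = h3; h3 = h2; h2 = h1; h1 = x;
      if (i >= 0) col[i] = x;
    }
  }
  return out;
}

// column-wise z-scoring with given statistics, one pass
// [[Rcpp::export(rng = false)]]
Rcpp::NumericMatrix znorm_cpp(const Rcpp::NumericMatrix& x,
                              const Rcpp::NumericVector& mu,
                              const Rcpp::NumericVector& sdev) {
  const R_xlen_t n = x.nrow(), p = x.ncol();
  Rcpp::NumericMatrix out(n, p);
  for (R_xlen_t j = 0; j < p; ++j) {
    const double m = mu[j], inv = 1.0 / sdev[j];
    const double* xi = &x(0, j);
    double* oi = &out(0, j);
    for (R_xlen_t i = 0; i < n; ++i) oi[i] = (xi[i] - m) * inv;
  }
  return out;
}

// one-pass |z|^2 of a complex matrix (the instantaneous power of an
// analytic signal), avoiding the intermediate copies of Re()^2 + Im()^2.
// Optionally restricted to the first n_rows rows and a column subset
// (1-based), so no intermediate full-size matrix is materialized.
// [[Rcpp::export(rng = false)]]
Rcpp::NumericMatrix cx_power_cpp(const Rcpp::ComplexMatrix& z,
                                 int n_rows = -1,
                                 Rcpp::Nullable<Rcpp::IntegerVector> cols =
                                     R_NilValue) {
  const R_xlen_t n = (n_rows < 0) ? z.nrow() : n_rows;
  Rcpp::IntegerVector cidx;
  if (cols.isNotNull()) {
    cidx = cols.get();
  } else {
    cidx = Rcpp::seq_len(z.ncol());
  }
  const R_xlen_t p = cidx.size();
  Rcpp::NumericMatrix out(n, p);
  for (R_xlen_t j = 0; j < p; ++j) {
    const Rcomplex* zi =
        reinterpret_cast<const Rcomplex*>(&z(0, cidx[j] - 1));
    double* oi = &out(0, j);
    for (R_xlen_t i = 0; i < n; ++i)
      oi[i] = zi[i].r * zi[i].r + zi[i].i * zi[i].i;
  }
  return out;
}
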