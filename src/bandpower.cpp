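#include <Rcpp.h>
#include <cmath>

// Fused squared-envelope + baseline z-score for the preprocessing fast
// path: given the analytic signal of one band (un-normalized inverse FFT,
// to be divided by `scale`), take |z|^2 / scale^2 of the first n_keep
// samples and z-score each channel with the mean/sd of the baseline rows
// [base_start, base_end] (1-based). One pass, one allocation.
// [[Rcpp::export(rng = false)]]
Rcpp::NumericMatrix power_znorm_cpp(const Rcpp::ComplexMatrix& env,
                                    double scale, int n_keep,
                                    int base_start, int base_end) {
  const R_xlen_t p = env.ncol();
  const double s2 = 1.0 / (scale * scale);
  Rcpp::NumericMatrix out(n_keep, p);
  const int b0 = base_start - 1, b1 = base_end - 1;
  const double nb = static_cast<double>(b1 - b0 + 1);
  for (R_xlen_t j = 0; j < p; ++j) {
    const Rcomplex* zj = reinterpret_cast<const Rcomplex*>(&env(0, j));
    double* oj = &out(0, j);
    for (int i = 0; i < n_keep; ++i)
      oj[i] = (zj[i].r * zj[i].r + zj[i].i * zj[i].i) * s2;
    double mu = 0;
    for (int i = b0; i <= b1; ++i) mu += oj[i];
    mu /= nb;
    double ss = 0;
    for (int i = b0; i <= b1; ++i) ss += (oj[i] - mu) * (oj[i] - mu);
    const double sd = std::sqrt(ss / (nb - 1));
    if (sd <= 0) Rcpp::stop("degenerate baseline: zero standard deviation");
    const double inv = 1.0 / sd;
    for (int i = 0; i < n_keep; ++i) oj[i] = (oj[i] - mu) * inv;
  }
  return out;
}
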