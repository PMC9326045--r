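#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Deterministic standard-normal noise: mt19937_64 with an explicit
// Box-Muller transform, so the stream is identical across platforms and
// standard-library versions (std::normal_distribution is not portable).
// Used for the bulk volume noise, where R's rnorm would dominate runtime.
// [[Rcpp::export]]
NumericVector gauss_noise_cpp(double n, int seed) {
  R_xlen_t len = (R_xlen_t)n;
  NumericVector out(len);
  std::mt19937_64 rng((uint64_t)seed);
  const double inv = 1.0 / 18446744073709551616.0;  // 2^-64
  const double two_pi = 6.283185307179586476925286766559;
  double* p = REAL(out);
  for (R_xlen_t i = 0; i < len; i += 2) {
    double u1 = ((double)rng() + 0.5) * inv;  // in (0, 1)
    double u2 = ((double)rng() + 0.5) * inv;
    double r = std::sqrt(-2.0 * std::log(u1));
    p[i] = r * std::cos(two_pi * u2);
    if (i + 1 < len) p[i + 1] = r * std::sin(two_pi * u2);
  }
  return out;
}
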