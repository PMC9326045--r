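#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Symmetric (mirror) boundary reflection: -1 -> 0, n -> n-1.  Conserves
// constant fields under a normalized kernel.
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// 1D convolution along one spatial axis of a flattened (nx, ny, nz, nt)
// array.  The kernel must have odd length and is applied with mirror
// boundaries.  Called once per axis for separable Gaussian smoothing.
// [[Rcpp::export]]
NumericVector conv_axis_cpp(NumericVector x, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nx = dims[0], ny = dims[1], nz = dims[2], nt = dims[3];
  const int L = kernel.size(), c = (L - 1) / 2;
  if (L % 2 == 0) stop("kernel length must be odd");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  NumericVector out(x.size());
  const int n[3] = {nx, ny, nz};
  const int nax = n[axis];
  const long strides[3] = {1L, (long)nx, (long)nx * ny};
  const long sv = (long)nx * ny * nz;
  const long sa = strides[axis];

  // Precompute reflected source positions for every output position.
  std::vector<int> tab((size_t)nax * L);
  for (int p = 0; p < nax; ++p)
    for (int l = 0; l < L; ++l)
      tab[(size_t)p * L + l] = reflect_idx(p + l - c, nax);

  const int oa1 = (axis == 0) ? 1 : 0;
  const int oa2 = (axis == 2) ? 1 : 2;
  const int n1 = n[oa1], n2 = n[oa2];
  const long s1 = strides[oa1], s2 = strides[oa2];
  const double* kp = REAL(kernel);
  const double* xp = REAL(x);
  double* op = REAL(out);
  std::vector<double> buf(nax);

  for (int t = 0; t < nt; ++t) {
    const long bt = (long)t * sv;
    for (int j2 = 0; j2 < n2; ++j2) {
      for (int j1 = 0; j1 < n1; ++j1) {
        const long base = bt + j1 * s1 + j2 * s2;
        for (int p = 0; p < nax; ++p) buf[p] = xp[base + p * sa];
        for (int p = 0; p < nax; ++p) {
          double acc = 0.0;
          const int* tp = &tab[(size_t)p * L];
          for (int l = 0; l < L; ++l) acc += kp[l] * buf[tp[l]];
          op[base + p * sa] = acc;
        }
      }
    }
  }
  return out;
}
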