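#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3D connected-component labeling of a logical volume by breadth-first
// search.  connectivity is 6 (faces), 18 (faces + edges) or 26 (faces +
// edges + corners).  Labels are assigned in scan order; callers impose
// their own canonical ordering afterwards.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector x, IntegerVector dims,
                                   int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long nv = (long)nx * ny * nz;
  if ((long)x.size() != nv) stop("mask size does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  // Neighbor offsets in (di, dj, dk).
  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int nz_cnt = (a != 0) + (b != 0) + (c != 0);
        if (nz_cnt == 0) continue;
        if (connectivity == 6 && nz_cnt > 1) continue;
        if (connectivity == 18 && nz_cnt > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  const int noff = (int)di.size();

  IntegerVector labels(nv);  // zero-initialized: background
  std::vector<long> stack;
  int cur = 0;
  const int* xp = LOGICAL(x);
  int* lp = INTEGER(labels);

  for (long s = 0; s < nv; ++s) {
    if (xp[s] != TRUE || lp[s] != 0) continue;
    ++cur;
    lp[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      int j = (int)((v / nx) % ny);
      int k = (int)(v / ((long)nx * ny));
      for (int o = 0; o < noff; ++o) {
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        long w = ii + (long)jj * nx + (long)kk * nx * ny;
        if (xp[w] == TRUE && lp[w] == 0) {
          lp[w] = cur;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
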