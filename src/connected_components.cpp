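#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 6-connected component labeling of a 3D logical array, iterative flood fill.
// Returns an integer vector of the same length: 0 outside the mask, component
// id (1-based, in discovery order) inside. NA in the mask is treated as FALSE.

// [[Rcpp::export]]
IntegerVector label_components_3d(LogicalVector mask, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  const R_xlen_t nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");

  IntegerVector labels(n);
  std::vector<R_xlen_t> stack;
  const R_xlen_t nxy = nx * ny;
  int comp = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (mask[start] != TRUE || labels[start] != 0) continue;
    ++comp;
    labels[start] = comp;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      R_xlen_t x = v % nx;
      R_xlen_t y = (v / nx) % ny;
      R_xlen_t z = v / nxy;
      R_xlen_t nb[6];
      int m = 0;
      if (x > 0)      nb[m++] = v - 1;
      if (x < nx - 1) nb[m++] = v + 1;
      if (y > 0)      nb[m++] = v - nx;
      if (y < ny - 1) nb[m++] = v + nx;
      if (z > 0)      nb[m++] = v - nxy;
      if (z < nz - 1) nb[m++] = v + nxy;
      for (int i = 0; i < m; ++i) {
        R_xlen_t w = nb[i];
        if (mask[w] == TRUE && labels[w] == 0) {
          labels[w] = comp;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}
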