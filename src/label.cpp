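#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Label connected components of a logical matrix by iterative flood fill.
// connectivity: 4 (edge neighbours) or 8 (edges + diagonals).
// Returns an integer matrix; background pixels are 0, components are
// numbered 1..n in order of first (column-major) encounter.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);

  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  const int nn = connectivity;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
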