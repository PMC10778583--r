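#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// 8-connected component labeling of a binary mask by iterative flood fill.
// Labels are assigned in column-major scan order starting at 1; background
// stays 0.  Diagonal neighbours belong to the same component.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next_label = 0;
  std::vector< std::pair<int, int> > stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next_label;
      lab(i, j) = next_label;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      while (!stack.empty()) {
        int ci = stack.back().first, cj = stack.back().second;
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next_label;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
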