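// 8-connected component labeling of a logical mask by breadth-first search.
// Caps are convex blobs; 8-connectivity avoids spurious splits across
// diagonal pixel steps.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> qx, qy;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qx.clear(); qy.clear();
      qx.push_back(i); qy.push_back(j);
      while (!qx.empty()) {
        int ci = qx.back(), cj = qy.back();
        qx.pop_back(); qy.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              qx.push_back(ni); qy.push_back(nj);
            }
          }
        }
      }
    }
  }
  return lab;
}
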