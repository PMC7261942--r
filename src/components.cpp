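#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling by breadth-first search.
// 2D: 8-connectivity; 3D: 26-connectivity.

// [[Rcpp::export]]
IntegerMatrix label_components_2d(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + nr * j);
      lab(i, j) = next;
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        int ci = cur % nr, cj = cur / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              stack.push_back(ni + nr * nj);
            }
          }
        }
      }
    }
  }
  return lab;
}

// mask: 3D array [slice, row, col] (column-major, dim attribute set)
// [[Rcpp::export]]
IntegerVector label_components_3d(const IntegerVector& mask) {
  IntegerVector dims = mask.attr("dim");
  const int ns = dims[0], nr = dims[1], nc = dims[2];
  IntegerVector lab(mask.size());
  lab.attr("dim") = dims;
  int next = 0;
  std::vector<int> stack;
  auto idx = [&](int s, int r, int c) { return s + ns * (r + nr * c); };
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int s = 0; s < ns; ++s) {
        int p = idx(s, r, c);
        if (mask[p] == 0 || lab[p] != 0) continue;
        ++next;
        stack.clear();
        stack.push_back(p);
        lab[p] = next;
        while (!stack.empty()) {
          int cur = stack.back(); stack.pop_back();
          int cs = cur % ns, rest = cur / ns;
          int cr = rest % nr, cc = rest / nr;
          for (int dc = -1; dc <= 1; ++dc) {
            for (int dr = -1; dr <= 1; ++dr) {
              for (int ds = -1; ds <= 1; ++ds) {
                if (ds == 0 && dr == 0 && dc == 0) continue;
                int zs = cs + ds, zr = cr + dr, zc = cc + dc;
                if (zs < 0 || zs >= ns || zr < 0 || zr >= nr ||
                    zc < 0 || zc >= nc) continue;
                int q = idx(zs, zr, zc);
                if (mask[q] != 0 && lab[q] == 0) {
                  lab[q] = next;
                  stack.push_back(q);
                }
              }
            }
          }
        }
      }
    }
  }
  return lab;
}
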