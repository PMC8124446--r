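// 8-connected component labeling of a binary mask (union-find, two pass).
// Labels are assigned in raster-scan order of each component's first pixel,
// so the result is deterministic.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {
int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}
void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a < b) parent[b] = a; else if (b < a) parent[a] = b;
}
} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_label_components8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 1;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // previously-scanned 8-neighbors (column-major scan)
      const int rr[4] = {r - 1, r - 1, r, r + 1};
      const int cc[4] = {c, c - 1, c - 1, c - 1};
      for (int k = 0; k < 4; ++k) {
        if (rr[k] < 0 || rr[k] >= nr || cc[k] < 0 || cc[k] >= nc) continue;
        int l = lab(rr[k], cc[k]);
        if (l > 0) {
          if (best == 0) best = l;
          else unite(parent, best, l);
        }
      }
      if (best == 0) {
        best = next++;
        parent.push_back(best);
      }
      lab(r, c) = best;
    }
  }
  // renumber roots in order of first appearance
  std::vector<int> newid(next, 0);
  int out = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = find_root(parent, l);
      if (newid[root] == 0) newid[root] = ++out;
      lab(r, c) = newid[root];
    }
  }
  return lab;
}
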