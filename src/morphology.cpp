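#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labelling with union-find.
// mask is a logical matrix (h x w, column-major); connectivity 4 or 8.

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 4) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix lab(h, w);
  std::vector<int> parent;
  parent.reserve(1024);
  parent.push_back(0); // label 0 = background

  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!mask(y, x)) continue;
      int up   = (y > 0 && mask(y - 1, x)) ? lab(y - 1, x) : 0;
      int left = (x > 0 && mask(y, x - 1)) ? lab(y, x - 1) : 0;
      int ul = 0, ur = 0;
      if (connectivity == 8) {
        ul = (y > 0 && x > 0 && mask(y - 1, x - 1)) ? lab(y - 1, x - 1) : 0;
        ur = (y < h - 1 && x > 0 && mask(y + 1, x - 1)) ? lab(y + 1, x - 1) : 0;
      }
      int nb[4] = {up, left, ul, ur};
      int assigned = 0;
      for (int k = 0; k < 4; ++k) {
        if (nb[k] > 0) {
          if (assigned == 0) assigned = nb[k];
          else uf_union(parent, assigned, nb[k]);
        }
      }
      if (assigned == 0) {
        assigned = (int)parent.size();
        parent.push_back(assigned);
      }
      lab(y, x) = assigned;
    }
  }

  // flatten and relabel consecutively
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (size_t i = 1; i < parent.size(); ++i) {
    int r = uf_find(parent, (int)i);
    if (remap[r] == 0 && r == (int)i) remap[r] = ++next;
  }
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (lab(y, x) > 0) lab(y, x) = remap[uf_find(parent, lab(y, x))];
  lab.attr("n") = next;
  return lab;
}

// Fill holes: background components not touching the border become
// foreground.

// [[Rcpp::export(name = ".fill_holes")]]
LogicalMatrix fill_holes(LogicalMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  LogicalMatrix inv(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      inv(y, x) = !mask(y, x);
  IntegerMatrix lab = cc_label(inv, 4);
  int n = lab.attr("n");
  std::vector<bool> touches(n + 1, false);
  for (int x = 0; x < w; ++x) {
    if (lab(0, x)) touches[lab(0, x)] = true;
    if (lab(h - 1, x)) touches[lab(h - 1, x)] = true;
  }
  for (int y = 0; y < h; ++y) {
    if (lab(y, 0)) touches[lab(y, 0)] = true;
    if (lab(y, w - 1)) touches[lab(y, w - 1)] = true;
  }
  LogicalMatrix out(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      out(y, x) = mask(y, x) || (lab(y, x) > 0 && !touches[lab(y, x)]);
  return out;
}

// Remove connected components smaller than min_area pixels.

// [[Rcpp::export(name = ".remove_small")]]
LogicalMatrix remove_small(LogicalMatrix mask, int min_area,
                           int connectivity = 4) {
  IntegerMatrix lab = cc_label(mask, connectivity);
  int n = lab.attr("n");
  const int h = mask.nrow(), w = mask.ncol();
  std::vector<int> area(n + 1, 0);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (lab(y, x)) area[lab(y, x)]++;
  LogicalMatrix out(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      out(y, x) = lab(y, x) > 0 && area[lab(y, x)] >= min_area;
  return out;
}
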