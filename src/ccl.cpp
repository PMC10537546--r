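#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Disjoint-set forest over provisional labels. Labels start at 1; index 0 unused.
static int uf_find(std::vector<int> &parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  // path compression
  while (parent[x] != root) {
    int nxt = parent[x];
    parent[x] = root;
    x = nxt;
  }
  return root;
}

// Union by smaller root label: the smaller (minority) label always wins,
// so resolved labels are reproducible regardless of merge order.
static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a);
  int rb = uf_find(parent, b);
  if (ra == rb) return;
  if (ra < rb) parent[rb] = ra; else parent[ra] = rb;
}

//' Two-pass Union-Find connected-component labeling (internal).
//'
//' Pass 1 scans the mask row by row from the top-left pixel, left to right.
//' Each foreground pixel inherits the smallest label among its already-visited
//' neighbors (NW, N, NE, W under 8-connectivity; N, W under 4-connectivity),
//' or opens a new label when none is labeled; conflicting labels are unioned.
//' Pass 2 replaces every provisional label by its root and compacts roots to
//' the contiguous range 1..K in raster order of first appearance.
//'
//' @param mask integer matrix of 0/1.
//' @param connectivity 8 (default, foreground) or 4 (used for hole detection).
//' @return integer matrix of labels, 0 = background.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix ccl_label(const IntegerMatrix &mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve(256);
  parent.push_back(0); // sentinel so labels index directly

  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (mask(r, c) == 0) continue;
      // already-visited neighbors in the forward raster mask
      int nr[4] = {r - 1, r - 1, r - 1, r};
      int nc[4] = {c - 1, c,     c + 1, c - 1};
      bool use[4] = {true, true, true, true};
      if (connectivity == 4) { use[0] = false; use[2] = false; }
      int labs[4];
      int nl = 0;
      for (int k = 0; k < 4; ++k) {
        if (!use[k]) continue;
        if (nr[k] < 0 || nc[k] < 0 || nc[k] >= W) continue;
        int l = lab(nr[k], nc[k]);
        if (l > 0) labs[nl++] = l;
      }
      if (nl == 0) {
        int fresh = (int) parent.size();
        parent.push_back(fresh);
        lab(r, c) = fresh;
      } else {
        int m = labs[0];
        for (int k = 1; k < nl; ++k) if (labs[k] < m) m = labs[k];
        lab(r, c) = m;
        for (int k = 0; k < nl; ++k) uf_union(parent, m, labs[k]);
      }
    }
  }

  // pass 2: resolve to roots, compact to 1..K in raster order of first occurrence
  std::vector<int> compact(parent.size(), 0);
  int K = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (compact[root] == 0) compact[root] = ++K;
      lab(r, c) = compact[root];
    }
  }
  return lab;
}
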