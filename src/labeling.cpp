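#include <Rcpp.h>
using namespace Rcpp;

// Two-pass union-find connected-component labeling, 8-connectivity.
// Final labels are compacted in raster-scan (row-major) order of first
// encounter, so label 1 is the component whose topmost-leftmost pixel
// comes first.

static int find_root(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];  // path halving
    x = parent[x];
  }
  return x;
}

static void unite(std::vector<int>& parent, int a, int b) {
  int ra = find_root(parent, a), rb = find_root(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent;
  parent.reserve(1024);
  std::vector<int> prov(static_cast<size_t>(H) * W, 0);  // provisional, col-major

  // first pass: raster scan (rows, then cols); neighbors already visited are
  // (r-1,c-1), (r-1,c), (r-1,c+1), (r,c-1)
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c)) continue;
      int best = -1;
      const int dr[4] = {-1, -1, -1, 0};
      const int dc[4] = {-1, 0, 1, -1};
      int neigh[4];
      int nn = 0;
      for (int k = 0; k < 4; ++k) {
        int rr = r + dr[k], cc = c + dc[k];
        if (rr < 0 || cc < 0 || cc >= W) continue;
        int p = prov[static_cast<size_t>(cc) * H + rr];
        if (p > 0) {
          neigh[nn++] = p - 1;
          if (best < 0 || p - 1 < best) best = p - 1;
        }
      }
      int id;
      if (best < 0) {
        id = static_cast<int>(parent.size());
        parent.push_back(id);
      } else {
        id = best;
        for (int k = 0; k < nn; ++k) unite(parent, id, neigh[k]);
      }
      prov[static_cast<size_t>(c) * H + r] = id + 1;
    }
  }

  // second pass: compact roots to 1..n in raster order of first encounter
  std::vector<int> compact(parent.size(), 0);
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int p = prov[static_cast<size_t>(c) * H + r];
      if (p == 0) continue;
      int root = find_root(parent, p - 1);
      if (compact[root] == 0) compact[root] = ++next;
      lab(r, c) = compact[root];
    }
  }
  return lab;
}
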