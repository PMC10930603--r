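#include <Rcpp.h>
using namespace Rcpp;

// Union-find connected-component labeling for 2-D (8-connectivity) and
// 3-D (26-connectivity) logical arrays. EBImage::bwlabel is 4-connective,
// which is not the convention used here.

static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// [[Rcpp::export(name = ".labelComponentsC")]]
IntegerVector labelComponentsC(LogicalVector mask, IntegerVector dim) {
  const int nd = dim.size();
  if (nd != 2 && nd != 3) stop("mask must be 2-D or 3-D");
  const int ny = dim[0], nx = dim[1], nz = (nd == 3) ? dim[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("dim does not match mask length");

  IntegerVector lab(n, 0);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background

  // scan order is column-major (y fastest), look back at already-seen neighbors
  for (int z = 0; z < nz; ++z) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        R_xlen_t idx = (R_xlen_t)z * ny * nx + (R_xlen_t)x * ny + y;
        if (!mask[idx]) continue;
        int best = 0;
        // neighbors with smaller linear index: dz in {-1,0}, and for dz==0
        // dx in {-1,0}, and for dz==0,dx==0 only dy==-1
        for (int dz = -1; dz <= 0; ++dz) {
          int zz = z + dz;
          if (zz < 0) continue;
          int dxmax = (dz == 0) ? 0 : 1;
          for (int dx = -1; dx <= dxmax; ++dx) {
            int xx = x + dx;
            if (xx < 0 || xx >= nx) continue;
            int dymax = (dz == 0 && dx == 0) ? -1 : 1;
            for (int dy = -1; dy <= dymax; ++dy) {
              int yy = y + dy;
              if (yy < 0 || yy >= ny) continue;
              R_xlen_t nidx = (R_xlen_t)zz * ny * nx + (R_xlen_t)xx * ny + yy;
              int nl = lab[nidx];
              if (nl > 0) {
                if (best == 0) best = nl;
                else uf_union(parent, best, nl);
              }
            }
          }
        }
        if (best == 0) {
          int newl = (int)parent.size();
          parent.push_back(newl);
          lab[idx] = newl;
        } else {
          lab[idx] = uf_find(parent, best);
        }
      }
    }
  }

  // flatten and renumber consecutively
  std::vector<int> newid(parent.size(), 0);
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (lab[i] > 0) {
      int r = uf_find(parent, lab[i]);
      if (newid[r] == 0) newid[r] = ++next;
      lab[i] = newid[r];
    }
  }
  lab.attr("dim") = dim;
  lab.attr("max") = next;
  return lab;
}

// Zhang-Suen thinning of a 2-D logical matrix to a 1-px skeleton.
// [[Rcpp::export(name = ".skeletonizeC")]]
LogicalMatrix skeletonizeC(LogicalMatrix input) {
  int ny = input.nrow(), nx = input.ncol();
  LogicalMatrix img(clone(input));
  bool changed = true;

  auto P = [&](int y, int x) -> int {
    if (y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return img(y, x) ? 1 : 0;
  };

  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
          if (!img(y, x)) continue;
          // neighbors p2..p9 clockwise from north
          int p2 = P(y - 1, x),     p3 = P(y - 1, x + 1);
          int p4 = P(y,     x + 1), p5 = P(y + 1, x + 1);
          int p6 = P(y + 1, x),     p7 = P(y + 1, x - 1);
          int p8 = P(y,     x - 1), p9 = P(y - 1, x - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(y, x));
        }
      }
      for (size_t i = 0; i < kill.size(); ++i) {
        img(kill[i].first, kill[i].second) = false;
        changed = true;
      }
    }
  }
  return img;
}
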