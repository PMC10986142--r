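#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <functional>
using namespace Rcpp;

// Signed Euclidean distance from every pixel centre to a closed polyline.
// Vertices are (row, col) in pixel-centred 0-based coordinates; the raster is
// nr x nc. Positive inside the polygon, negative outside (even-odd rule).
// Exact point-to-segment distance: no rasterization of the contour.
// [[Rcpp::export]]
NumericMatrix signed_distance_cpp(NumericMatrix vertices, int nr, int nc) {
  const int nv = vertices.nrow();
  std::vector<double> vr(nv), vc(nv);
  for (int i = 0; i < nv; ++i) { vr[i] = vertices(i, 0); vc[i] = vertices(i, 1); }

  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const double pr = r, pc = c;
      double best = R_PosInf;
      bool inside = false;
      for (int i = 0; i < nv; ++i) {
        const int j = (i + 1) % nv;
        const double ar = vr[i], ac = vc[i], br = vr[j], bc = vc[j];
        // distance to segment a-b
        const double dr = br - ar, dc = bc - ac;
        const double len2 = dr * dr + dc * dc;
        double t = 0.0;
        if (len2 > 0.0) {
          t = ((pr - ar) * dr + (pc - ac) * dc) / len2;
          if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
        }
        const double qr = ar + t * dr - pr, qc = ac + t * dc - pc;
        const double d2 = qr * qr + qc * qc;
        if (d2 < best) best = d2;
        // even-odd crossing test on the column axis
        if ((ar > pr) != (br > pr)) {
          const double xc = ac + (pr - ar) / (br - ar) * (bc - ac);
          if (pc < xc) inside = !inside;
        }
      }
      out(r, c) = inside ? std::sqrt(best) : -std::sqrt(best);
    }
  }
  return out;
}

// 8-connected component labelling of a logical/integer raster (two-pass
// union-find). Background is 0/FALSE; labels are 1..K in first-encounter order.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      // neighbours already visited in column-major order:
      // (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
      int neigh[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      int cur = 0;
      for (int k = 0; k < 4; ++k) {
        const int rr = neigh[k][0], cc = neigh[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        const int l = lab(rr, cc);
        if (l > 0) {
          if (cur == 0) cur = l; else unite(cur, l);
        }
      }
      if (cur == 0) {
        cur = (int)parent.size();
        parent.push_back(cur);
      }
      lab(r, c) = cur;
    }
  }
  // relabel to consecutive ids
  std::vector<int> remap(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c) > 0) {
        const int root = find(lab(r, c));
        if (remap[root] == 0) remap[root] = ++next;
        lab(r, c) = remap[root];
      }
  return lab;
}
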