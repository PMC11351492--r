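#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
// 1-D transform of sampled function f; result in d. Squared distances stay
// integer-valued throughout, so the 2-D composition is exact.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared EDT of a binary mask; pixels outside the canvas count as background,
// so the transform is computed on a 1-px zero-padded copy and cropped back.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const int Hp = H + 2, Wp = W + 2;
  const double INF = 1e18;
  std::vector<double> g(Hp * Wp, 0.0);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (mask(i, j)) g[(j + 1) * Hp + (i + 1)] = INF;

  std::vector<double> f(std::max(Hp, Wp)), d(std::max(Hp, Wp));
  // columns
  for (int j = 0; j < Wp; ++j) {
    for (int i = 0; i < Hp; ++i) f[i] = g[j * Hp + i];
    dt1d(f, d, Hp);
    for (int i = 0; i < Hp; ++i) g[j * Hp + i] = d[i];
  }
  // rows
  for (int i = 0; i < Hp; ++i) {
    for (int j = 0; j < Wp; ++j) f[j] = g[j * Hp + i];
    dt1d(f, d, Wp);
    for (int j = 0; j < Wp; ++j) g[j * Hp + i] = d[j];
  }
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      out(i, j) = std::round(g[(j + 1) * Hp + (i + 1)]);
  return out;
}

// Local thickness (Hildebrand-Ruegsegger, disk/diameter convention):
// T(p) = max{ 2*R(c) : c foreground, |p-c| <= R(c) } with R(c) the Euclidean
// distance from c to the nearest background pixel (canvas border = background).
// Disks wholly contained in a neighbour's disk are skipped (distance ridge);
// the containment test R(c') >= R(c) + |c-c'| only ever drops redundant
// centers, so the map equals the full enumeration exactly.
// [[Rcpp::export]]
NumericMatrix local_thickness_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  NumericMatrix d2 = edt_sq_cpp(mask);
  NumericMatrix out(H, W);
  const double sqrt2 = std::sqrt(2.0), eps = 1e-7;

  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      const double R2 = d2(i, j);
      const double R = std::sqrt(R2);
      // ridge test against 8 neighbours
      bool redundant = false;
      for (int dj = -1; dj <= 1 && !redundant; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0) continue;
          int ni = i + di, nj = j + dj;
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (!mask(ni, nj)) continue;
          double dist = (di != 0 && dj != 0) ? sqrt2 : 1.0;
          if (std::sqrt(d2(ni, nj)) >= R + dist + eps) { redundant = true; break; }
        }
      }
      if (redundant) continue;
      // paint the disk
      int r = (int)std::floor(R);
      double diam = 2.0 * R;
      for (int dj = -r; dj <= r; ++dj) {
        int nj = j + dj;
        if (nj < 0 || nj >= W) continue;
        for (int di = -r; di <= r; ++di) {
          int ni = i + di;
          if (ni < 0 || ni >= H) continue;
          if (!mask(ni, nj)) continue;
          if ((double)(di * di + dj * dj) <= R2 && out(ni, nj) < diam)
            out(ni, nj) = diam;
        }
      }
    }
  }
  return out;
}

// ---- 8-connected component labeling (two-pass union-find) ----
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Labels are renumbered 1..L in order of each component's first pixel in
// column-major scan; callers re-sort as needed.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      // previously scanned 8-neighbours: (i-1,j), (i-1,j-1), (i,j-1), (i+1,j-1)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int lmin = 0;
      for (int t = 0; t < 4; ++t) {
        int ni = nb[t][0], nj = nb[t][1];
        if (ni < 0 || ni >= H || nj < 0) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          int r = uf_find(parent, l);
          if (lmin == 0 || r < lmin) lmin = r;
        }
      }
      if (lmin == 0) {
        parent.push_back(next);
        lab(i, j) = next++;
      } else {
        lab(i, j) = lmin;
        for (int t = 0; t < 4; ++t) {
          int ni = nb[t][0], nj = nb[t][1];
          if (ni < 0 || ni >= H || nj < 0) continue;
          int l = lab(ni, nj);
          if (l > 0) {
            int r = uf_find(parent, l);
            if (r != lmin) parent[r] = lmin;
          }
        }
      }
    }
  }
  // flatten and renumber in order of first appearance
  std::vector<int> newlab(next, 0);
  int L = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l);
      if (newlab[r] == 0) newlab[r] = ++L;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
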