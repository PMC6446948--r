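#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

// Union-find with path compression for connected-component sizes.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, std::vector<int> &sz, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra == rb) return;
  if (sz[ra] < sz[rb]) std::swap(ra, rb);
  parent[rb] = ra;
  sz[ra] += sz[rb];
}

// Neighbour offsets for 6/18/26-connectivity. Only "earlier" neighbours
// (negative lexicographic offsets) are needed for the union pass, but we
// enumerate all and filter by linear index below.
static void neighbour_offsets(int connectivity, std::vector<std::array<int,3>> &offs) {
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        offs.push_back({dx, dy, dz});
      }
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector field, IntegerVector dims,
                       double E, double H, double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (field.size() != n) stop("field length does not match dims");

  double fmax = 0.0;
  for (int i = 0; i < n; i++) {
    if (field[i] < 0) stop("field must be non-negative");
    if (field[i] > fmax) fmax = field[i];
  }
  NumericVector out(n);
  if (fmax <= 0 || dh <= 0) return out;

  std::vector<std::array<int,3>> offs;
  neighbour_offsets(connectivity, offs);

  std::vector<int> parent(n), sz(n);
  const int nsteps = (int) std::floor(fmax / dh + 1e-12);

  for (int s = 1; s <= nsteps; s++) {
    const double h = s * dh;
    // label the suprathreshold set {field >= h}
    for (int i = 0; i < n; i++) { parent[i] = i; sz[i] = 1; }
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++)
        for (int x = 0; x < nx; x++) {
          const int i = x + nx * (y + ny * z);
          if (field[i] < h) continue;
          for (size_t k = 0; k < offs.size(); k++) {
            const int xx = x + offs[k][0], yy = y + offs[k][1], zz = z + offs[k][2];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              continue;
            const int j = xx + nx * (yy + ny * zz);
            if (j < i && field[j] >= h) uf_union(parent, sz, i, j);
          }
        }
    const double hH = std::pow(h, H);
    for (int i = 0; i < n; i++) {
      if (field[i] < h) continue;
      const int root = uf_find(parent, i);
      out[i] += std::pow((double) sz[root], E) * hH * dh;
    }
  }
  return out;
}
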