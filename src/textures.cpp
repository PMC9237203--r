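#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Levels are stored as a flat integer vector over a 3D bounding box,
// column-major (x fastest), with NA_INTEGER marking voxels outside the VOI.
// All neighbourhood definitions are 26-connected (Chebyshev distance 1).

static inline int idx3(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

// The 13 unique direction vectors (one of each +/- pair), lexicographic.
static const int DIRS13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export]]
IntegerVector cpp_glcm(IntegerVector levels, IntegerVector dims, int ng) {
  int d[3] = {dims[0], dims[1], dims[2]};
  IntegerVector out(Dimension(ng, ng, 13));
  for (int dir = 0; dir < 13; ++dir) {
    const int dx = DIRS13[dir][0], dy = DIRS13[dir][1], dz = DIRS13[dir][2];
    int* M = out.begin() + (R_xlen_t)dir * ng * ng;
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int g1 = levels[idx3(x, y, z, d)];
          if (g1 == NA_INTEGER) continue;
          int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (x2 < 0 || x2 >= d[0] || y2 < 0 || y2 >= d[1] ||
              z2 < 0 || z2 >= d[2]) continue;
          int g2 = levels[idx3(x2, y2, z2, d)];
          if (g2 == NA_INTEGER) continue;
          // symmetric: count the pair in both orders
          M[(g1 - 1) + ng * (g2 - 1)] += 1;
          M[(g2 - 1) + ng * (g1 - 1)] += 1;
        }
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_glrlm(IntegerVector levels, IntegerVector dims, int ng) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int maxlen = std::max(d[0], std::max(d[1], d[2]));
  IntegerVector out(Dimension(ng, maxlen, 13));
  for (int dir = 0; dir < 13; ++dir) {
    const int dx = DIRS13[dir][0], dy = DIRS13[dir][1], dz = DIRS13[dir][2];
    int* M = out.begin() + (R_xlen_t)dir * ng * maxlen;
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int g = levels[idx3(x, y, z, d)];
          if (g == NA_INTEGER) continue;
          // start of a run only if the predecessor is absent or different
          int xp = x - dx, yp = y - dy, zp = z - dz;
          if (xp >= 0 && xp < d[0] && yp >= 0 && yp < d[1] &&
              zp >= 0 && zp < d[2]) {
            int gp = levels[idx3(xp, yp, zp, d)];
            if (gp == g) continue;
          }
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (xn >= 0 && xn < d[0] && yn >= 0 && yn < d[1] &&
                 zn >= 0 && zn < d[2] &&
                 levels[idx3(xn, yn, zn, d)] == g) {
            ++len; xn += dx; yn += dy; zn += dz;
          }
          M[(g - 1) + ng * (len - 1)] += 1;
        }
  }
  return out;
}

// Connected components (26-connectivity) of equal grey level.
// Returns zone label per voxel (0 outside VOI), labels 1..n_zones.
// [[Rcpp::export]]
IntegerVector cpp_zone_labels(IntegerVector levels, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int n = d[0] * d[1] * d[2];
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int i0 = idx3(x, y, z, d);
        if (levels[i0] == NA_INTEGER || lab[i0] != 0) continue;
        int g = levels[i0];
        lab[i0] = ++next;
        stack.clear();
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int cx = i % d[0], cy = (i / d[0]) % d[1], cz = i / (d[0] * d[1]);
          for (int dz2 = -1; dz2 <= 1; ++dz2)
            for (int dy2 = -1; dy2 <= 1; ++dy2)
              for (int dx2 = -1; dx2 <= 1; ++dx2) {
                if (dx2 == 0 && dy2 == 0 && dz2 == 0) continue;
                int nx = cx + dx2, ny = cy + dy2, nz = cz + dz2;
                if (nx < 0 || nx >= d[0] || ny < 0 || ny >= d[1] ||
                    nz < 0 || nz >= d[2]) continue;
                int j = idx3(nx, ny, nz, d);
                if (lab[j] == 0 && levels[j] == g) {
                  lab[j] = next;
                  stack.push_back(j);
                }
              }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Chebyshev distance from each VOI voxel to the nearest non-VOI voxel
// (voxels outside the image count as border). Exact two-pass chamfer
// transform for the L-infinity metric. Minimum distance is 1.
// [[Rcpp::export]]
IntegerVector cpp_cheb_border_dist(IntegerVector levels, IntegerVector dims) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int n = d[0] * d[1] * d[2];
  const int BIG = 1 << 28;
  std::vector<int> dist(n);
  for (int i = 0; i < n; ++i)
    dist[i] = (levels[i] == NA_INTEGER) ? 0 : BIG;
  // forward pass
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int i = idx3(x, y, z, d);
        if (dist[i] == 0) continue;
        int best = dist[i];
        for (int dz2 = -1; dz2 <= 1; ++dz2)
          for (int dy2 = -1; dy2 <= 1; ++dy2)
            for (int dx2 = -1; dx2 <= 1; ++dx2) {
              // causal neighbours only (already visited in raster order)
              if (dz2 > 0 || (dz2 == 0 && dy2 > 0) ||
                  (dz2 == 0 && dy2 == 0 && dx2 >= 0)) continue;
              int nx = x + dx2, ny = y + dy2, nz = z + dz2;
              int nd;
              if (nx < 0 || nx >= d[0] || ny < 0 || ny >= d[1] ||
                  nz < 0 || nz >= d[2]) nd = 0;  // outside image = border
              else nd = dist[idx3(nx, ny, nz, d)];
              if (nd + 1 < best) best = nd + 1;
            }
        dist[i] = best;
      }
  // backward pass
  for (int z = d[2] - 1; z >= 0; --z)
    for (int y = d[1] - 1; y >= 0; --y)
      for (int x = d[0] - 1; x >= 0; --x) {
        int i = idx3(x, y, z, d);
        if (dist[i] == 0) continue;
        int best = dist[i];
        for (int dz2 = -1; dz2 <= 1; ++dz2)
          for (int dy2 = -1; dy2 <= 1; ++dy2)
            for (int dx2 = -1; dx2 <= 1; ++dx2) {
              if (dz2 < 0 || (dz2 == 0 && dy2 < 0) ||
                  (dz2 == 0 && dy2 == 0 && dx2 <= 0)) continue;
              int nx = x + dx2, ny = y + dy2, nz = z + dz2;
              int nd;
              if (nx < 0 || nx >= d[0] || ny < 0 || ny >= d[1] ||
                  nz < 0 || nz >= d[2]) nd = 0;
              else nd = dist[idx3(nx, ny, nz, d)];
              if (nd + 1 < best) best = nd + 1;
            }
        dist[i] = best;
      }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dist[i];
  out.attr("dim") = dims;
  return out;
}

// NGTDM accumulators: n_i (voxel count per level, voxels with >= 1 in-VOI
// neighbour) and s_i (sum of |level - mean neighbour level|).
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector levels, IntegerVector dims, int ng) {
  int d[3] = {dims[0], dims[1], dims[2]};
  NumericVector ni(ng), si(ng);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int g = levels[idx3(x, y, z, d)];
        if (g == NA_INTEGER) continue;
        double sum = 0; int cnt = 0;
        for (int dz2 = -1; dz2 <= 1; ++dz2)
          for (int dy2 = -1; dy2 <= 1; ++dy2)
            for (int dx2 = -1; dx2 <= 1; ++dx2) {
              if (dx2 == 0 && dy2 == 0 && dz2 == 0) continue;
              int nx = x + dx2, ny = y + dy2, nz = z + dz2;
              if (nx < 0 || nx >= d[0] || ny < 0 || ny >= d[1] ||
                  nz < 0 || nz >= d[2]) continue;
              int gn = levels[idx3(nx, ny, nz, d)];
              if (gn == NA_INTEGER) continue;
              sum += gn; ++cnt;
            }
        if (cnt == 0) continue;  // isolated voxels excluded
        ni[g - 1] += 1.0;
        si[g - 1] += std::abs((double)g - sum / cnt);
      }
  return List::create(_["n"] = ni, _["s"] = si);
}

// NGLDM dependence-count matrix: rows = grey level, cols = dependence
// count k = 0..26 (number of 26-neighbours with |level diff| <= alpha).
// [[Rcpp::export]]
IntegerMatrix cpp_ngldm(IntegerVector levels, IntegerVector dims, int ng,
                        int alpha) {
  int d[3] = {dims[0], dims[1], dims[2]};
  IntegerMatrix M(ng, 27);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int g = levels[idx3(x, y, z, d)];
        if (g == NA_INTEGER) continue;
        int k = 0;
        for (int dz2 = -1; dz2 <= 1; ++dz2)
          for (int dy2 = -1; dy2 <= 1; ++dy2)
            for (int dx2 = -1; dx2 <= 1; ++dx2) {
              if (dx2 == 0 && dy2 == 0 && dz2 == 0) continue;
              int nx = x + dx2, ny = y + dy2, nz = z + dz2;
              if (nx < 0 || nx >= d[0] || ny < 0 || ny >= d[1] ||
                  nz < 0 || nz >= d[2]) continue;
              int gn = levels[idx3(nx, ny, nz, d)];
              if (gn == NA_INTEGER) continue;
              if (std::abs(gn - g) <= alpha) ++k;
            }
        M(g - 1, k) += 1;
      }
  return M;
}
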