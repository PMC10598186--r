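// Compiled kernels for 3D binary image processing and phantom rasterization.
// All arrays are in R's column-major order with dims (nx, ny, nz); voxel
// indices are 0-based internally.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <queue>
#include <limits>

using namespace Rcpp;

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Connected-component labelling, 26-connectivity.
// Labels are assigned in raster-scan seed order, so the component containing
// the lexicographically smallest voxel index gets label 1, etc.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t seed = 0; seed < n; ++seed) {
    if (!mask[seed] || lab[seed]) continue;
    ++next;
    lab[seed] = next;
    stack.push_back((int)seed);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            int w = lin(xx, yy, zz, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
          }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Ellipsoidal dilation / erosion (structuring element radii in voxels per
// axis). Outside the image is treated as background.

static std::vector<std::array<int,3> > ellipsoid_offsets(int rx, int ry, int rz) {
  std::vector<std::array<int,3> > off;
  for (int dz = -rz; dz <= rz; ++dz)
    for (int dy = -ry; dy <= ry; ++dy)
      for (int dx = -rx; dx <= rx; ++dx) {
        double s = 0.0;
        if (rx) s += (double)dx * dx / ((double)rx * rx); else if (dx) s = 2;
        if (ry) s += (double)dy * dy / ((double)ry * ry); else if (dy) s = 2;
        if (rz) s += (double)dz * dz / ((double)rz * rz); else if (dz) s = 2;
        if (s <= 1.0) off.push_back({dx, dy, dz});
      }
  return off;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, IntegerVector dims,
                         IntegerVector rvox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  auto off = ellipsoid_offsets(rvox[0], rvox[1], rvox[2]);
  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
    for (size_t k = 0; k < off.size(); ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        continue;
      out[lin(xx, yy, zz, nx, ny)] = true;
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, IntegerVector dims,
                        IntegerVector rvox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  auto off = ellipsoid_offsets(rvox[0], rvox[1], rvox[2]);
  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) {
    if (!mask[v]) continue;
    int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
    bool all = true;
    for (size_t k = 0; k < off.size() && all; ++k) {
      int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
        all = false;
      else if (!mask[lin(xx, yy, zz, nx, ny)])
        all = false;
    }
    if (all) out[v] = true;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Chamfer 3-4-5 distance transform: distance of foreground voxels to the
// nearest background voxel (image border counts as background).
// [[Rcpp::export]]
IntegerVector cpp_chamfer_dt(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int INF = std::numeric_limits<int>::max() / 4;
  IntegerVector dt(n);
  for (R_xlen_t v = 0; v < n; ++v) dt[v] = mask[v] ? INF : 0;

  // neighbour half-masks with chamfer weights
  struct Nb { int dx, dy, dz, w; };
  std::vector<Nb> fwd;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        // strictly "before" in raster order
        if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)))) {
          int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
          fwd.push_back({dx, dy, dz, a == 1 ? 3 : (a == 2 ? 4 : 5)});
        }
      }

  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int v = lin(x, y, z, nx, ny);
        if (dt[v] == 0) continue;
        int best = dt[v];
        for (size_t k = 0; k < fwd.size(); ++k) {
          int xx = x + fwd[k].dx, yy = y + fwd[k].dy, zz = z + fwd[k].dz;
          int d = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                   zz >= nz) ? 0 : dt[lin(xx, yy, zz, nx, ny)];
          if (d + fwd[k].w < best) best = d + fwd[k].w;
        }
        dt[v] = best;
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int v = lin(x, y, z, nx, ny);
        if (dt[v] == 0) continue;
        int best = dt[v];
        for (size_t k = 0; k < fwd.size(); ++k) {
          int xx = x - fwd[k].dx, yy = y - fwd[k].dy, zz = z - fwd[k].dz;
          int d = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                   zz >= nz) ? 0 : dt[lin(xx, yy, zz, nx, ny)];
          if (d + fwd[k].w < best) best = d + fwd[k].w;
        }
        dt[v] = best;
      }
  return dt;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning (curve skeleton).
//
// A voxel is "simple" (removable without changing topology) when the object
// in its 26-neighbourhood has exactly one 26-connected component and the
// background restricted to its 18-neighbourhood has exactly one 6-connected
// component that is 6-adjacent to the voxel (Bertrand & Malandain
// characterization). Voxels are peeled in increasing chamfer-distance order
// (distance-ordered homotopic thinning), preserving curve endpoints
// (<= 1 object 26-neighbour), which yields a centred one-voxel-thick
// centreline.

static const int N18_OK[27] = {
  // |dx|+|dy|+|dz| in {1,2}; index = (dx+1) + 3*(dy+1) + 9*(dz+1)
  0,1,0, 1,1,1, 0,1,0,
  1,1,1, 1,0,1, 1,1,1,
  0,1,0, 1,1,1, 0,1,0
};

static bool is_simple(const int* occ /*27 cells, centre occ ignored*/) {
  // occ[idx] = 1 if object; idx = (dx+1) + 3*(dy+1) + 9*(dz+1)
  // --- object 26-components in N26 ---
  int seen[27] = {0};
  int ncomp = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !occ[i] || seen[i]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    int stack[27], top = 0;
    stack[top++] = i; seen[i] = 1;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2)
              continue;
            int j = xx + 3 * yy + 9 * zz;
            if (j == 13 || j == c || !occ[j] || seen[j]) continue;
            seen[j] = 1; stack[top++] = j;
          }
    }
  }
  if (ncomp != 1) return false;

  // --- background 6-components in N18, 6-adjacent to centre ---
  int bseen[27] = {0};
  int nbg = 0;
  static const int faces[6] = {13 - 1, 13 + 1, 13 - 3, 13 + 3, 13 - 9, 13 + 9};
  for (int f = 0; f < 6; ++f) {
    int i = faces[f];
    if (occ[i] || bseen[i]) continue;
    ++nbg;
    if (nbg > 1) return false;
    int stack[27], top = 0;
    stack[top++] = i; bseen[i] = 1;
    while (top) {
      int c = stack[--top];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + d6[k][0], yy = cy + d6[k][1], zz = cz + d6[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int j = xx + 3 * yy + 9 * zz;
        if (j == 13 || !N18_OK[j] || occ[j] || bseen[j]) continue;
        bseen[j] = 1; stack[top++] = j;
      }
    }
  }
  return nbg == 1;
}

// Geodesic chamfer distance (3-4-5 weights) from a seed voxel, inside the
// mask. Dijkstra over the 26-neighbourhood.
// [[Rcpp::export]]
IntegerVector cpp_geodesic_dt(LogicalVector mask, IntegerVector dims,
                              int seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int INF = std::numeric_limits<int>::max() / 4;
  IntegerVector gd(n, INF);
  if (!mask[seed]) stop("seed voxel is not inside the mask");
  typedef std::pair<int, int> QE;  // (dist, voxel)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  gd[seed] = 0;
  pq.push(QE(0, seed));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int d = top.first, v = top.second;
    if (d > gd[v]) continue;
    int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
              zz >= nz) continue;
          int w = lin(xx, yy, zz, nx, ny);
          if (!mask[w]) continue;
          int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
          int nd = d + (a == 1 ? 3 : (a == 2 ? 4 : 5));
          if (nd < gd[w]) { gd[w] = nd; pq.push(QE(nd, w)); }
        }
  }
  for (R_xlen_t v = 0; v < n; ++v) if (!mask[v]) gd[v] = NA_INTEGER;
  return gd;
}

// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims, int seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<uint8_t> obj(n);
  for (R_xlen_t v = 0; v < n; ++v) obj[v] = mask[v] ? 1 : 0;
  IntegerVector dt = cpp_chamfer_dt(mask, dims);

  // anchor voxels: the seed plus one voxel per local-maximum plateau of the
  // geodesic distance from the seed (= one per branch tip). Anchors are
  // never removed, so thinning cannot erode a branch away even when the
  // mask is perfectly symmetric and no curve endpoint ever forms.
  IntegerVector gd = cpp_geodesic_dt(mask, dims, seed);
  std::vector<uint8_t> anchor(n, 0);
  anchor[seed] = 1;
  {
    std::vector<uint8_t> ismax(n, 0);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int v = lin(x, y, z, nx, ny);
          if (!mask[v] || gd[v] == NA_INTEGER) continue;
          bool mx = true;
          for (int dz = -1; dz <= 1 && mx; ++dz)
            for (int dy = -1; dy <= 1 && mx; ++dy)
              for (int dx = -1; dx <= 1 && mx; ++dx) {
                if (!dx && !dy && !dz) continue;
                int xx = x + dx, yy = y + dy, zz = z + dz;
                if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                    zz >= nz) continue;
                int w = lin(xx, yy, zz, nx, ny);
                if (mask[w] && gd[w] != NA_INTEGER && gd[w] > gd[v])
                  mx = false;
              }
          if (mx) ismax[v] = 1;
        }
    // one anchor per connected plateau of local maxima: the lowest index
    std::vector<uint8_t> seen(n, 0);
    std::vector<int> stack;
    for (R_xlen_t s = 0; s < n; ++s) {
      if (!ismax[s] || seen[s]) continue;
      anchor[s] = 1;
      stack.push_back((int)s); seen[s] = 1;
      while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                  zz >= nz) continue;
              int w = lin(xx, yy, zz, nx, ny);
              if (ismax[w] && !seen[w]) { seen[w] = 1; stack.push_back(w); }
            }
      }
    }
  }

  auto occ_of = [&](int x, int y, int z, int* occ) {
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          int idx = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          occ[idx] = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                      zz >= nz) ? 0 : obj[lin(xx, yy, zz, nx, ny)];
        }
  };
  auto nbr_count = [&](int x, int y, int z) {
    int c = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          c += obj[lin(xx, yy, zz, nx, ny)];
        }
    return c;
  };

  // directional sub-iterations: in each sub-cycle only voxels whose
  // background 6-neighbour lies in the designated direction are candidates
  // (frozen at sub-cycle start). This limits erosion along a structure's
  // axis to one layer per iteration while still letting redundant lateral
  // columns collapse, so even-width shapes thin to a single centred line
  // without losing their ends.
  const int dstep[6][3] = {{0,0,1},{0,0,-1},{0,1,0},{0,-1,0},{1,0,0},{-1,0,0}};
  bool changed = true;
  std::vector<std::pair<int,int> > cand;  // (dt, linear index)
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      cand.clear();
      const int ddx = dstep[dir][0], ddy = dstep[dir][1], ddz = dstep[dir][2];
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int v = lin(x, y, z, nx, ny);
            if (!obj[v]) continue;
            int xx = x + ddx, yy = y + ddy, zz = z + ddz;
            bool bg = (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                       zz >= nz) || !obj[lin(xx, yy, zz, nx, ny)];
            if (bg) cand.push_back(std::make_pair(dt[v], v));
          }
      std::sort(cand.begin(), cand.end());
      int occ[27];
      for (size_t k = 0; k < cand.size(); ++k) {
        int v = cand[k].second;
        if (!obj[v] || anchor[v]) continue;
        int z = v / (nx * ny), rem = v % (nx * ny), y = rem / nx, x = rem % nx;
        if (nbr_count(x, y, z) <= 1) continue;  // curve endpoint: keep
        occ_of(x, y, z, occ);
        if (is_simple(occ)) { obj[v] = 0; changed = true; }
      }
    }
  }

  LogicalVector out(n, false);
  for (R_xlen_t v = 0; v < n; ++v) out[v] = obj[v] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Trilinear interpolation at world-mm points. Points outside the volume get
// `fill` and inside = FALSE.
// [[Rcpp::export]]
List cpp_trilinear(NumericVector vol, IntegerVector dims,
                   NumericVector spacing, NumericVector origin,
                   NumericMatrix pts, double fill) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = pts.nrow();
  NumericVector val(np);
  LogicalVector inside(np);
  for (int i = 0; i < np; ++i) {
    double vx = (pts(i, 0) - origin[0]) / spacing[0];
    double vy = (pts(i, 1) - origin[1]) / spacing[1];
    double vz = (pts(i, 2) - origin[2]) / spacing[2];
    if (vx < 0 || vy < 0 || vz < 0 ||
        vx > nx - 1 || vy > ny - 1 || vz > nz - 1) {
      val[i] = fill; inside[i] = false; continue;
    }
    int x0 = (int)std::floor(vx), y0 = (int)std::floor(vy),
        z0 = (int)std::floor(vz);
    if (x0 == nx - 1) --x0;
    if (y0 == ny - 1) --y0;
    if (z0 == nz - 1) --z0;
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    double fx = vx - x0, fy = vy - y0, fz = vz - z0;
    int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
        z1 = std::min(z0 + 1, nz - 1);
    double c000 = vol[lin(x0, y0, z0, nx, ny)], c100 = vol[lin(x1, y0, z0, nx, ny)];
    double c010 = vol[lin(x0, y1, z0, nx, ny)], c110 = vol[lin(x1, y1, z0, nx, ny)];
    double c001 = vol[lin(x0, y0, z1, nx, ny)], c101 = vol[lin(x1, y0, z1, nx, ny)];
    double c011 = vol[lin(x0, y1, z1, nx, ny)], c111 = vol[lin(x1, y1, z1, nx, ny)];
    double c00 = c000 * (1 - fx) + c100 * fx, c10 = c010 * (1 - fx) + c110 * fx;
    double c01 = c001 * (1 - fx) + c101 * fx, c11 = c011 * (1 - fx) + c111 * fx;
    double c0 = c00 * (1 - fy) + c10 * fy, c1 = c01 * (1 - fy) + c11 * fy;
    val[i] = c0 * (1 - fz) + c1 * fz;
    inside[i] = true;
  }
  return List::create(Named("values") = val, Named("inside") = inside);
}

// ---------------------------------------------------------------------------
// Phantom tube-tree rasterizer.
//
// `samples` holds a fine polyline sampling of every branch centreline:
// columns x, y, z (mm) and lumen radius r (mm). The radial intensity model
// places the Gaussian wall peak at c = r + sigma*sqrt(2*log(2)) so that the
// inner half-maximum radius of the wall equals the declared lumen radius r:
//   rho <= c : HU = lumen + (peak - lumen)   * exp(-(rho-c)^2 / (2 sigma^2))
//   rho >  c : HU = background + (peak - background) * exp(-(rho-c)^2/(2 s^2))
// HU is evaluated on an `ss`-times supersampled grid and block-averaged;
// `inside_frac` is the per-native-voxel fraction of subvoxels with rho <= r.
// [[Rcpp::export]]
List cpp_rasterize(IntegerVector dims, NumericVector spacing,
                   NumericVector origin, NumericMatrix samples,
                   double lumen, double peak, double background,
                   double sigma, int ss) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int sx = nx * ss, sy = ny * ss, sz = nz * ss;
  const R_xlen_t ns = (R_xlen_t)sx * sy * sz;
  const double px = spacing[0] / ss, py = spacing[1] / ss, pz = spacing[2] / ss;
  // subvoxel (0,0,0) centre so that block averages align with native centres
  const double ox = origin[0] - spacing[0] / 2.0 + px / 2.0;
  const double oy = origin[1] - spacing[1] / 2.0 + py / 2.0;
  const double oz = origin[2] - spacing[2] / 2.0 + pz / 2.0;
  const float BIG = 1e30f;
  std::vector<float> mind(ns, BIG), rat(ns, 0.0f);
  const double co = sigma * std::sqrt(2.0 * std::log(2.0));

  const int npt = samples.nrow();
  for (int i = 0; i < npt; ++i) {
    double cxm = samples(i, 0), cym = samples(i, 1), czm = samples(i, 2);
    double r = samples(i, 3);
    double R = r + co + 3.5 * sigma;
    int x0 = std::max(0, (int)std::floor((cxm - R - ox) / px));
    int x1 = std::min(sx - 1, (int)std::ceil((cxm + R - ox) / px));
    int y0 = std::max(0, (int)std::floor((cym - R - oy) / py));
    int y1 = std::min(sy - 1, (int)std::ceil((cym + R - oy) / py));
    int z0 = std::max(0, (int)std::floor((czm - R - oz) / pz));
    int z1 = std::min(sz - 1, (int)std::ceil((czm + R - oz) / pz));
    for (int z = z0; z <= z1; ++z) {
      double dz = oz + z * pz - czm;
      for (int y = y0; y <= y1; ++y) {
        double dy = oy + y * py - cym;
        double dyz2 = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)sx * (y + (R_xlen_t)sy * z);
        for (int x = x0; x <= x1; ++x) {
          double dx = ox + x * px - cxm;
          double d2 = dx * dx + dyz2;
          R_xlen_t v = base + x;
          float d = (float)std::sqrt(d2);
          if (d < mind[v]) { mind[v] = d; rat[v] = (float)r; }
        }
      }
    }
  }

  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector hu(n);
  NumericVector frac(n);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        double acc = 0.0; int nin = 0;
        for (int kz = 0; kz < ss; ++kz)
          for (int ky = 0; ky < ss; ++ky)
            for (int kx = 0; kx < ss; ++kx) {
              R_xlen_t v = (R_xlen_t)(x * ss + kx) +
                (R_xlen_t)sx * ((y * ss + ky) + (R_xlen_t)sy * (z * ss + kz));
              double d = mind[v];
              if (d >= 1e29) { acc += background; continue; }
              double r = rat[v], c = r + co;
              double g = std::exp(-(d - c) * (d - c) * inv2s2);
              acc += (d <= c) ? lumen + (peak - lumen) * g
                              : background + (peak - background) * g;
              if (d <= r) ++nin;
            }
        double m = (double)ss * ss * ss;
        R_xlen_t v = lin(x, y, z, nx, ny);
        hu[v] = acc / m;
        frac[v] = nin / m;
      }
  return List::create(Named("hu") = hu, Named("inside_frac") = frac);
}
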