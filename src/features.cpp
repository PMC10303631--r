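#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel grids arrive as column-major integer vectors with 0 outside the
// mask and quantized levels 1..Ng inside. All texture kernels accumulate
// raw counts; normalization and feature algebra happen in R.

static inline int vidx(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// The 13 unique 3D direction offsets (one per antipodal pair), ordered
// lexicographically by (dz, dy, dx) with the first nonzero positive.
static void unique_offsets(int off[13][3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
          off[n][0] = dx; off[n][1] = dy; off[n][2] = dz; ++n;
        }
      }
}

// [[Rcpp::export]]
NumericVector cpp_glcm(IntegerVector lev, IntegerVector dim, int ng, int dist) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int off[13][3];
  unique_offsets(off);
  NumericVector out(ng * ng * 13); // counts of ordered pairs along +offset
  for (int d = 0; d < 13; ++d) {
    int dx = off[d][0] * dist, dy = off[d][1] * dist, dz = off[d][2] * dist;
    for (int z = 0; z < nz; ++z) {
      int z2 = z + dz; if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          int x2 = x + dx; if (x2 < 0 || x2 >= nx) continue;
          int a = lev[vidx(x, y, z, nx, ny)];
          if (a == 0) continue;
          int b = lev[vidx(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1.0;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int off[13][3];
  unique_offsets(off);
  int lmax = std::max(nx, std::max(ny, nz));
  NumericVector out(ng * lmax * 13); // run counts: level x run length x direction
  for (int d = 0; d < 13; ++d) {
    int dx = off[d][0], dy = off[d][1], dz = off[d][2];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int g = lev[vidx(x, y, z, nx, ny)];
          if (g == 0) continue;
          // run starts where the previous voxel along the direction is
          // outside the grid, outside the mask, or a different level
          int px = x - dx, py = y - dy, pz = z - dz;
          bool prev_same = px >= 0 && px < nx && py >= 0 && py < ny &&
                           pz >= 0 && pz < nz &&
                           lev[vidx(px, py, pz, nx, ny)] == g;
          if (prev_same) continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 &&
                 cz < nz && lev[vidx(cx, cy, cz, nx, ny)] == g) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          out[(g - 1) + ng * (len - 1) + ng * lmax * d] += 1.0;
        }
  }
  return out;
}

// Connected zones (26-connectivity) of identical gray level.
// Returns a matrix with one row per zone: (level, size).
// [[Rcpp::export]]
IntegerMatrix cpp_glszm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<int> zl, zs, stack;
  for (int i = 0; i < n; ++i) {
    if (lev[i] == 0 || seen[i]) continue;
    int g = lev[i];
    int size = 0;
    stack.clear();
    stack.push_back(i);
    seen[i] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int cz = cur / (nx * ny), rem = cur % (nx * ny);
      int cy = rem / nx, cx = rem % nx;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            int j = vidx(x2, y2, z2, nx, ny);
            if (!seen[j] && lev[j] == g) { seen[j] = 1; stack.push_back(j); }
          }
    }
    zl.push_back(g);
    zs.push_back(size);
  }
  IntegerMatrix out(zl.size(), 2);
  for (size_t k = 0; k < zl.size(); ++k) { out(k, 0) = zl[k]; out(k, 1) = zs[k]; }
  return out;
}

// Per level: count of voxels with >= 1 in-mask 26-neighbor (n_i) and the
// summed absolute difference between the level and the mean neighbor
// level (s_i).
// [[Rcpp::export]]
NumericMatrix cpp_ngtdm(IntegerVector lev, IntegerVector dim, int ng) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = lev[vidx(x, y, z, nx, ny)];
        if (g == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int h = lev[vidx(x2, y2, z2, nx, ny)];
              if (h > 0) { sum += h; ++cnt; }
            }
        if (cnt == 0) continue; // isolated voxels carry no gray-tone difference
        out(g - 1, 0) += 1.0;
        out(g - 1, 1) += std::fabs((double)g - sum / cnt);
      }
  return out;
}

// Dependence counts: for each in-mask voxel, the number of in-mask
// 26-neighbors whose level differs from the center by <= alpha.
// Column d+1 holds the count of voxels with d dependent neighbors.
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector lev, IntegerVector dim, int ng,
                       int alpha) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericMatrix out(ng, 27); // d in 0..26
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int g = lev[vidx(x, y, z, nx, ny)];
        if (g == 0) continue;
        int dcount = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              int h = lev[vidx(x2, y2, z2, nx, ny)];
              if (h > 0 && std::abs(h - g) <= alpha) ++dcount;
            }
        out(g - 1, dcount) += 1.0;
      }
  return out;
}

// ---- iso-surface mesh (marching tetrahedra) --------------------------------
// A scalar field sampled at voxel centers (here: the anti-aliased binary
// mask, padded so the surface closes) is iso-surfaced at `iso`: vertices
// sit on cell edges where the field crosses the level, at linearly
// interpolated positions. Each cell of 8 voxel centers is split into 6
// tetrahedra sharing the main diagonal; per tetrahedron the level set is
// empty, a triangle, or a quad. Triangles are oriented outward by
// checking the normal against the inside-vertex centroid, giving a
// closed surface whose divergence-theorem volume is well defined.

struct P3 { double x, y, z; };

static inline P3 edge_cross(const P3 &a, const P3 &b, double va, double vb,
                            double iso) {
  double t = (vb == va) ? 0.5 : (iso - va) / (vb - va);
  P3 m = { a.x + t * (b.x - a.x), a.y + t * (b.y - a.y),
           a.z + t * (b.z - a.z) };
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_iso_mesh(NumericVector field, IntegerVector dim,
                           NumericVector spacing, double iso) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // cube corner offsets
  const int co[8][3] = { {0,0,0}, {1,0,0}, {1,1,0}, {0,1,0},
                         {0,0,1}, {1,0,1}, {1,1,1}, {0,1,1} };
  // 6 tetrahedra sharing diagonal 0-6
  const int tets[6][4] = { {0,1,2,6}, {0,2,3,6}, {0,3,7,6},
                           {0,7,4,6}, {0,4,5,6}, {0,5,1,6} };
  double area = 0.0, volume = 0.0;
  std::vector<P3> tri; tri.reserve(6);
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double v[8]; P3 p[8];
        int nin_cell = 0;
        for (int c = 0; c < 8; ++c) {
          int cx = x + co[c][0], cy = y + co[c][1], cz = z + co[c][2];
          v[c] = field[vidx(cx, cy, cz, nx, ny)];
          if (v[c] > iso) ++nin_cell;
          p[c].x = cx * sx; p[c].y = cy * sy; p[c].z = cz * sz;
        }
        if (nin_cell == 0 || nin_cell == 8) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = tets[t];
          int nin = 0, nout = 0, iin[4], iout[4];
          for (int c = 0; c < 4; ++c) {
            if (v[T[c]] > iso) iin[nin++] = T[c]; else iout[nout++] = T[c];
          }
          if (nin == 0 || nin == 4) continue;
          tri.clear();
          if (nin == 1) {
            P3 a = edge_cross(p[iin[0]], p[iout[0]], v[iin[0]], v[iout[0]], iso);
            P3 b = edge_cross(p[iin[0]], p[iout[1]], v[iin[0]], v[iout[1]], iso);
            P3 c = edge_cross(p[iin[0]], p[iout[2]], v[iin[0]], v[iout[2]], iso);
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          } else if (nin == 3) {
            P3 a = edge_cross(p[iin[0]], p[iout[0]], v[iin[0]], v[iout[0]], iso);
            P3 b = edge_cross(p[iin[1]], p[iout[0]], v[iin[1]], v[iout[0]], iso);
            P3 c = edge_cross(p[iin[2]], p[iout[0]], v[iin[2]], v[iout[0]], iso);
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
          } else { // 2 in, 2 out: quad -> two triangles
            P3 a = edge_cross(p[iin[0]], p[iout[0]], v[iin[0]], v[iout[0]], iso);
            P3 b = edge_cross(p[iin[0]], p[iout[1]], v[iin[0]], v[iout[1]], iso);
            P3 c = edge_cross(p[iin[1]], p[iout[1]], v[iin[1]], v[iout[1]], iso);
            P3 d = edge_cross(p[iin[1]], p[iout[0]], v[iin[1]], v[iout[0]], iso);
            tri.push_back(a); tri.push_back(b); tri.push_back(c);
            tri.push_back(a); tri.push_back(c); tri.push_back(d);
          }
          // centroid of inside vertices (orientation reference)
          P3 cin = {0, 0, 0};
          for (int c = 0; c < nin; ++c) {
            cin.x += p[iin[c]].x; cin.y += p[iin[c]].y; cin.z += p[iin[c]].z;
          }
          cin.x /= nin; cin.y /= nin; cin.z /= nin;
          for (size_t k = 0; k + 2 < tri.size(); k += 3) {
            P3 p1 = tri[k], p2 = tri[k + 1], p3 = tri[k + 2];
            double ux = p2.x - p1.x, uy = p2.y - p1.y, uz = p2.z - p1.z;
            double wx = p3.x - p1.x, wy = p3.y - p1.y, wz = p3.z - p1.z;
            double nxv = uy * wz - uz * wy;
            double nyv = uz * wx - ux * wz;
            double nzv = ux * wy - uy * wx;
            double gx = (p1.x + p2.x + p3.x) / 3.0 - cin.x;
            double gy = (p1.y + p2.y + p3.y) / 3.0 - cin.y;
            double gz = (p1.z + p2.z + p3.z) / 3.0 - cin.z;
            if (nxv * gx + nyv * gy + nzv * gz < 0) {
              // flip to outward orientation
              P3 tmp = p2; p2 = p3; p3 = tmp;
              nxv = -nxv; nyv = -nyv; nzv = -nzv;
            }
            double a2 = std::sqrt(nxv * nxv + nyv * nyv + nzv * nzv);
            area += 0.5 * a2;
            volume += (p1.x * nxv + p1.y * nyv + p1.z * nzv) / 6.0;
          }
        }
      }
  NumericVector out(2);
  out[0] = area;
  out[1] = std::fabs(volume);
  return out;
}

// Max pairwise distances among surface voxels (those with < 6 in-mask
// 6-neighbors): full 3D and within planes of fixed z (slice), fixed y
// (column) and fixed x (row).
// [[Rcpp::export]]
NumericVector cpp_max_diameters(IntegerVector mask, IntegerVector dim,
                                NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<int> X, Y, Z;
  const int six[6][3] = { {1,0,0}, {-1,0,0}, {0,1,0}, {0,-1,0}, {0,0,1}, {0,0,-1} };
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (!mask[vidx(x, y, z, nx, ny)]) continue;
        int nn = 0;
        for (int s = 0; s < 6; ++s) {
          int x2 = x + six[s][0], y2 = y + six[s][1], z2 = z + six[s][2];
          if (x2 >= 0 && x2 < nx && y2 >= 0 && y2 < ny && z2 >= 0 && z2 < nz &&
              mask[vidx(x2, y2, z2, nx, ny)])
            ++nn;
        }
        if (nn < 6) { X.push_back(x); Y.push_back(y); Z.push_back(z); }
      }
  size_t n = X.size();
  double d3 = 0, dslice = 0, dcol = 0, drow = 0;
  for (size_t i = 0; i < n; ++i)
    for (size_t j = i + 1; j < n; ++j) {
      double ddx = (X[i] - X[j]) * sx;
      double ddy = (Y[i] - Y[j]) * sy;
      double ddz = (Z[i] - Z[j]) * sz;
      double q = ddx * ddx + ddy * ddy + ddz * ddz;
      if (q > d3) d3 = q;
      if (Z[i] == Z[j] && ddx * ddx + ddy * ddy > dslice)
        dslice = ddx * ddx + ddy * ddy;
      if (Y[i] == Y[j] && ddx * ddx + ddz * ddz > dcol)
        dcol = ddx * ddx + ddz * ddz;
      if (X[i] == X[j] && ddy * ddy + ddz * ddz > drow)
        drow = ddy * ddy + ddz * ddz;
    }
  NumericVector out(4);
  out[0] = std::sqrt(d3);
  out[1] = std::sqrt(dslice);
  out[2] = std::sqrt(dcol);
  out[3] = std::sqrt(drow);
  return out;
}
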