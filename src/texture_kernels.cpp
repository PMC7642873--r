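#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Voxel-lattice kernels shared by the texture-matrix families.
// `levels` is a 3D integer array (column-major, dim attribute set in R):
// 0 outside the ROI, 1..ng inside. Offsets are in voxel units; no mm
// correction is applied for texture (shape features handle spacing in R).

// 13 unique 3D offsets (full 26-neighbourhood modulo sign).
static const int DIRS[13][3] = {
  {1,0,0},{0,1,0},{0,0,1},
  {1,1,0},{1,-1,0},{1,0,1},{1,0,-1},{0,1,1},{0,1,-1},
  {1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}
};

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector levels, int nx, int ny, int nz, int ng) {
  // Symmetrised pair counts, ng x ng x 13.
  NumericVector out(ng * ng * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *slab = &out[d * ng * ng];
    for (int z = 0; z < nz; ++z) {
      int z2 = z + dz; if (z2 < 0 || z2 >= nz) continue;
      for (int y = 0; y < ny; ++y) {
        int y2 = y + dy; if (y2 < 0 || y2 >= ny) continue;
        for (int x = 0; x < nx; ++x) {
          int x2 = x + dx; if (x2 < 0 || x2 >= nx) continue;
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          int b = levels[idx3(x2, y2, z2, nx, ny)];
          if (b == 0) continue;
          slab[(a - 1) + ng * (b - 1)] += 1.0;
          slab[(b - 1) + ng * (a - 1)] += 1.0;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, 13);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector levels, int nx, int ny, int nz, int ng) {
  // Run-length counts per direction: ng x maxlen x 13. A run is a maximal
  // collinear sequence of equal nonzero levels; out-of-ROI voxels break runs.
  int maxlen = std::max(nx, std::max(ny, nz));
  // diagonal runs can be at most min over the involved axes, <= maxlen anyway
  NumericVector out(ng * maxlen * 13);
  for (int d = 0; d < 13; ++d) {
    const int dx = DIRS[d][0], dy = DIRS[d][1], dz = DIRS[d][2];
    double *slab = &out[d * ng * maxlen];
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int a = levels[idx3(x, y, z, nx, ny)];
          if (a == 0) continue;
          // run start: predecessor out of bounds / out of ROI / different level
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz &&
              levels[idx3(px, py, pz, nx, ny)] == a)
            continue;
          int len = 1;
          int cx = x + dx, cy = y + dy, cz = z + dz;
          while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz &&
                 levels[idx3(cx, cy, cz, nx, ny)] == a) {
            ++len; cx += dx; cy += dy; cz += dz;
          }
          slab[(a - 1) + ng * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, 13);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_glszm_counts(IntegerVector levels, int nx, int ny, int nz, int ng) {
  // 26-connected constant-level zones; counts ng x maxsize.
  int n = nx * ny * nz;
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int,int> > zones; // (level, size)
  std::vector<int> stack;
  int maxsize = 1;
  for (int s = 0; s < n; ++s) {
    if (seen[s] || levels[s] == 0) continue;
    int lev = levels[s];
    int size = 0;
    stack.clear(); stack.push_back(s); seen[s] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int q = idx3(x2, y2, z2, nx, ny);
            if (!seen[q] && levels[q] == lev) { seen[q] = 1; stack.push_back(q); }
          }
    }
    zones.push_back(std::make_pair(lev, size));
    if (size > maxsize) maxsize = size;
  }
  NumericMatrix out(ng, maxsize);
  for (size_t i = 0; i < zones.size(); ++i)
    out(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gldm_counts(IntegerVector levels, int nx, int ny, int nz,
                              int ng, int alpha) {
  // Dependence d of a voxel = number of 26-neighbours inside the ROI whose
  // level differs by at most alpha (center excluded). Matrix ng x 27,
  // column j = d + 1.
  NumericMatrix out(ng, 27);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        int d = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b != 0 && std::abs(b - a) <= alpha) ++d;
            }
        out(a - 1, d) += 1.0;
      }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ngtdm_stats(IntegerVector levels, int nx, int ny, int nz, int ng) {
  // Per level i: n_i (count of ROI voxels of level i having >= 1 in-ROI
  // neighbour) and s_i = sum over those voxels of |i - mean(neighbour levels)|.
  NumericMatrix out(ng, 2);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int a = levels[idx3(x, y, z, nx, ny)];
        if (a == 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x2 = x + dx, y2 = y + dy, z2 = z + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
              int b = levels[idx3(x2, y2, z2, nx, ny)];
              if (b != 0) { sum += b; ++cnt; }
            }
        if (cnt > 0) {
          out(a - 1, 0) += 1.0;
          out(a - 1, 1) += std::fabs((double)a - sum / cnt);
        }
      }
  return out;
}

// ---- Mesh surface via marching tetrahedra -------------------------------

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double w[3] = { u[1]*v[2]-u[2]*v[1], u[2]*v[0]-u[0]*v[2], u[0]*v[1]-u[1]*v[0] };
  return 0.5 * std::sqrt(w[0]*w[0] + w[1]*w[1] + w[2]*w[2]);
}

static inline void midpoint(const double a[3], const double b[3], double m[3]) {
  m[0] = 0.5*(a[0]+b[0]); m[1] = 0.5*(a[1]+b[1]); m[2] = 0.5*(a[2]+b[2]);
}

static inline double tet_vol(const double a[3], const double b[3],
                             const double c[3], const double d[3]) {
  double u[3] = { b[0]-a[0], b[1]-a[1], b[2]-a[2] };
  double v[3] = { c[0]-a[0], c[1]-a[1], c[2]-a[2] };
  double w[3] = { d[0]-a[0], d[1]-a[1], d[2]-a[2] };
  double det = u[0]*(v[1]*w[2]-v[2]*w[1]) - u[1]*(v[0]*w[2]-v[2]*w[0])
             + u[2]*(v[0]*w[1]-v[1]*w[0]);
  return std::fabs(det) / 6.0;
}

static inline void lerp_cross(const double a[3], double fa,
                              const double b[3], double fb,
                              double c, double q[3]) {
  double t = (c - fa) / (fb - fa);
  q[0] = a[0] + t*(b[0]-a[0]); q[1] = a[1] + t*(b[1]-a[1]); q[2] = a[2] + t*(b[2]-a[2]);
}

// [[Rcpp::export]]
NumericVector cpp_mesh_area_volume(NumericVector field, int nx, int ny, int nz,
                                   double sx, double sy, double sz) {
  // Iso-surface at 0.5 of a scalar field sampled at voxel centers, padded by
  // one background (zero) layer so the surface closes. Marching tetrahedra:
  // each grid cube splits into six tetrahedra sharing the main diagonal; the
  // level set of the linear interpolant inside a tetrahedron is a triangle or
  // a quad, and the enclosed region is convex, so its volume decomposes into
  // tetrahedra from an inside vertex.
  const double iso = 0.5;
  const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
  };
  const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
  };
  double area = 0.0, volume = 0.0;
  #define FVAL(X,Y,Z) (((X) < 1 || (X) > nx || (Y) < 1 || (Y) > ny || (Z) < 1 || (Z) > nz) ? 0.0 : \
    field[idx3((X)-1, (Y)-1, (Z)-1, nx, ny)])
  for (int z = 0; z <= nz; ++z)
    for (int y = 0; y <= ny; ++y)
      for (int x = 0; x <= nx; ++x) {
        double f[8]; bool any = false, all = true;
        for (int c = 0; c < 8; ++c) {
          f[c] = FVAL(x + corner[c][0], y + corner[c][1], z + corner[c][2]);
          if (f[c] > iso) any = true; else all = false;
        }
        if (!any) continue;
        double p[8][3];
        for (int c = 0; c < 8; ++c) {
          p[c][0] = (x + corner[c][0]) * sx;
          p[c][1] = (y + corner[c][1]) * sy;
          p[c][2] = (z + corner[c][2]) * sz;
        }
        double vtet = sx * sy * sz / 6.0;
        if (all) { volume += 6.0 * vtet; continue; }
        for (int t = 0; t < 6; ++t) {
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            int ci = tets[t][c];
            if (f[ci] > iso) in[nin++] = ci; else out[nout++] = ci;
          }
          if (nin == 0) continue;
          if (nin == 4) { volume += vtet; continue; }
          if (nin == 1) {
            const int a = in[0];
            double q1[3], q2[3], q3[3], frac = 1.0;
            lerp_cross(p[a], f[a], p[out[0]], f[out[0]], iso, q1);
            lerp_cross(p[a], f[a], p[out[1]], f[out[1]], iso, q2);
            lerp_cross(p[a], f[a], p[out[2]], f[out[2]], iso, q3);
            for (int k = 0; k < 3; ++k)
              frac *= (iso - f[a]) / (f[out[k]] - f[a]);
            area += tri_area(q1, q2, q3);
            volume += vtet * frac;
          } else if (nin == 3) {
            const int o = out[0];
            double q1[3], q2[3], q3[3], frac = 1.0;
            lerp_cross(p[o], f[o], p[in[0]], f[in[0]], iso, q1);
            lerp_cross(p[o], f[o], p[in[1]], f[in[1]], iso, q2);
            lerp_cross(p[o], f[o], p[in[2]], f[in[2]], iso, q3);
            for (int k = 0; k < 3; ++k)
              frac *= (iso - f[o]) / (f[in[k]] - f[o]);
            area += tri_area(q1, q2, q3);
            volume += vtet * (1.0 - frac);
          } else { // nin == 2: inside {a,b}, outside {c,d}
            const int a = in[0], b = in[1], cc = out[0], dd = out[1];
            double q1[3], q2[3], q3[3], q4[3];
            lerp_cross(p[a], f[a], p[cc], f[cc], iso, q1); // ac
            lerp_cross(p[a], f[a], p[dd], f[dd], iso, q2); // ad
            lerp_cross(p[b], f[b], p[dd], f[dd], iso, q3); // bd
            lerp_cross(p[b], f[b], p[cc], f[cc], iso, q4); // bc
            // iso quad cycles (ac, bc, bd, ad) = (q1, q4, q3, q2)
            area += tri_area(q1, q4, q3) + tri_area(q1, q3, q2);
            // convex inside region, star-shaped from a; boundary faces not
            // through a: triangle (b,q4,q3) and the iso quad
            volume += tet_vol(p[a], p[b], q4, q3)
                    + tet_vol(p[a], q1, q4, q3)
                    + tet_vol(p[a], q1, q3, q2);
          }
        }
      }
  #undef FVAL
  return NumericVector::create(area, volume);
}

// [[Rcpp::export]]
NumericVector cpp_max_diameters(IntegerMatrix vox, double sx, double sy, double sz) {
  // vox: m x 3 zero-based voxel indices of surface voxels. Returns
  // (max3D, maxSlice [xy, per z], maxColumn [yz, per x], maxRow [xz, per y]).
  int m = vox.nrow();
  double d3 = 0.0, dsl = 0.0, dco = 0.0, dro = 0.0;
  for (int i = 0; i < m; ++i) {
    double xi = vox(i,0)*sx, yi = vox(i,1)*sy, zi = vox(i,2)*sz;
    for (int j = i + 1; j < m; ++j) {
      double dx = xi - vox(j,0)*sx, dy = yi - vox(j,1)*sy, dz = zi - vox(j,2)*sz;
      double dd = dx*dx + dy*dy + dz*dz;
      if (dd > d3) d3 = dd;
      if (vox(i,2) == vox(j,2)) { double q = dx*dx + dy*dy; if (q > dsl) dsl = q; }
      if (vox(i,0) == vox(j,0)) { double q = dy*dy + dz*dz; if (q > dco) dco = q; }
      if (vox(i,1) == vox(j,1)) { double q = dx*dx + dz*dz; if (q > dro) dro = q; }
    }
  }
  return NumericVector::create(std::sqrt(d3), std::sqrt(dsl),
                               std::sqrt(dco), std::sqrt(dro));
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int nx, int ny, int nz) {
  // 26-connected component labels of a binary mask (0 background); used for
  // ROI contiguity checks.
  int n = nx * ny * nz;
  IntegerVector lab(n);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    stack.clear(); stack.push_back(s); lab[s] = next;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int cx = cur % nx, cy = (cur / nx) % ny, cz = cur / (nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            int x2 = cx + dx, y2 = cy + dy, z2 = cz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz) continue;
            int q = idx3(x2, y2, z2, nx, ny);
            if (mask[q] != 0 && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("dim") = IntegerVector::create(nx, ny, nz);
  return lab;
}
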