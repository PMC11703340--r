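// Low-level 3D morphometry primitives: exact Euclidean distance transform,
// local (largest-inscribed-sphere) thickness, 26-connected component
// labelling and marching-tetrahedra isosurface area.  All grids are passed
// as flat vectors in R's column-major order with explicit dimensions.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

static inline int sub2ind(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Felzenszwalb & Huttenlocher 1D squared distance transform (lower envelope
// of parabolas).  f is overwritten with the transformed values.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[kk]] + (double)v[kk] * v[kk])) /
          (2.0 * q - 2.0 * v[kk]);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < (double)q) ++kk;
    double dq = (double)q - (double)v[kk];
    d[q] = dq * dq + f[v[kk]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Squared Euclidean distance (in voxel units) from each foreground voxel to
// the nearest background voxel centre.  Voxels outside the grid count as
// background (zero-padding convention).
// [[Rcpp::export(name = ".edt3d_cpp")]]
NumericVector edt3d_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e30;
  NumericVector g(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); ++i) g[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x: 1D exact distance with implicit background at both ends
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        int idx = sub2ind(i, j, k, nx, ny);
        // distance to virtual background just outside the grid
        double dedge = std::min((double)(i + 1), (double)(nx - i));
        f[i] = mask[idx] ? dedge * dedge : 0.0;
      }
      // exact 1D: scan for runs; simpler to use two sweeps since values are
      // 0 or edge-limited: forward/backward propagation
      for (int i = 1; i < nx; ++i) {
        double cand = std::sqrt(f[i - 1]) + 1.0;
        if (cand * cand < f[i]) f[i] = cand * cand;
      }
      for (int i = nx - 2; i >= 0; --i) {
        double cand = std::sqrt(f[i + 1]) + 1.0;
        if (cand * cand < f[i]) f[i] = cand * cand;
      }
      for (int i = 0; i < nx; ++i) g[sub2ind(i, j, k, nx, ny)] = f[i];
    }

  // pass along y
  f.assign(nmax, 0.0);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        double dedge = std::min((double)(j + 1), (double)(ny - j));
        f[j] = std::min(g[sub2ind(i, j, k, nx, ny)], dedge * dedge);
      }
      dt1d(f, d, v, z);
      for (int j = 0; j < ny; ++j) g[sub2ind(i, j, k, nx, ny)] = f[j];
    }

  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) {
        double dedge = std::min((double)(k + 1), (double)(nz - k));
        f[k] = std::min(g[sub2ind(i, j, k, nx, ny)], dedge * dedge);
      }
      dt1d(f, d, v, z);
      for (int k = 0; k < nz; ++k) g[sub2ind(i, j, k, nx, ny)] = f[k];
    }

  return g;
}

// Hildebrand-Rueegsegger local thickness: for every foreground voxel, the
// diameter (in voxels) of the largest inscribed sphere that contains it.
// Spheres are painted largest-first; a sphere anchored at a voxel with
// centre-to-background distance r covers voxels within r - 1/2 and assigns
// diameter 2r - 1 (so an n-voxel slab reports thickness n).
// [[Rcpp::export(name = ".local_thickness_cpp")]]
NumericVector local_thickness_cpp(IntegerVector mask, NumericVector edt2,
                                  IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector th(mask.size());
  std::vector<int> fg;
  fg.reserve(mask.size() / 4);
  for (int idx = 0; idx < (int)mask.size(); ++idx)
    if (mask[idx]) fg.push_back(idx);
  std::sort(fg.begin(), fg.end(), [&](int a, int b) {
    return edt2[a] > edt2[b];
  });
  for (int c : fg) {
    double r = std::sqrt(edt2[c]);
    double val = 2.0 * r - 1.0;
    double reach = r - 0.5;
    if (reach < 0) reach = 0;
    int ci = c % nx, cj = (c / nx) % ny, ck = c / (nx * ny);
    int R = (int)std::floor(reach);
    double reach2 = reach * reach;
    for (int dk = -R; dk <= R; ++dk) {
      int k = ck + dk;
      if (k < 0 || k >= nz) continue;
      for (int dj = -R; dj <= R; ++dj) {
        int j = cj + dj;
        if (j < 0 || j >= ny) continue;
        double d2kj = (double)dk * dk + (double)dj * dj;
        if (d2kj > reach2) continue;
        int dimax = (int)std::floor(std::sqrt(reach2 - d2kj));
        for (int di = -dimax; di <= dimax; ++di) {
          int i = ci + di;
          if (i < 0 || i >= nx) continue;
          int idx = sub2ind(i, j, k, nx, ny);
          if (mask[idx] && th[idx] < val) th[idx] = val;
        }
      }
    }
    if (th[c] < val) th[c] = val;  // R = 0 case: at least covers itself
  }
  return th;
}

// 26-connected component labelling (iterative DFS).  Returns labels
// 1..n_components, 0 for background.
// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(IntegerVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size());
  std::vector<int> stack;
  int next = 0;
  for (int start = 0; start < (int)mask.size(); ++start) {
    if (!mask[start] || lab[start]) continue;
    ++next;
    lab[start] = next;
    stack.push_back(start);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int ci = cur % nx, cj = (cur / nx) % ny, ck = cur / (nx * ny);
      for (int dk = -1; dk <= 1; ++dk) {
        int k = ck + dk;
        if (k < 0 || k >= nz) continue;
        for (int dj = -1; dj <= 1; ++dj) {
          int j = cj + dj;
          if (j < 0 || j >= ny) continue;
          for (int di = -1; di <= 1; ++di) {
            int i = ci + di;
            if (i < 0 || i >= nx) continue;
            int idx = sub2ind(i, j, k, nx, ny);
            if (mask[idx] && !lab[idx]) {
              lab[idx] = next;
              stack.push_back(idx);
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

static double tri_area(const double *p1, const double *p2, const double *p3) {
  double u[3], w[3], c[3];
  for (int i = 0; i < 3; ++i) { u[i] = p2[i] - p1[i]; w[i] = p3[i] - p1[i]; }
  c[0] = u[1] * w[2] - u[2] * w[1];
  c[1] = u[2] * w[0] - u[0] * w[2];
  c[2] = u[0] * w[1] - u[1] * w[0];
  return 0.5 * std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
}

// Marching tetrahedra isosurface area at the given level.  Each grid cell is
// split into 6 tetrahedra around the main diagonal; crossing points are
// placed by linear interpolation.  The field should be zero-padded by the
// caller so the surface closes at the grid boundary.
// [[Rcpp::export(name = ".mt_surface_area_cpp")]]
double mt_surface_area_cpp(NumericVector field, IntegerVector dims,
                           double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // 6-tet decomposition of the unit cube around diagonal corner0-corner7;
  // corner bit order: bit0 = x, bit1 = y, bit2 = z.
  static const int tets[6][4] = {
    {0, 1, 5, 7}, {0, 5, 4, 7}, {0, 4, 6, 7},
    {0, 6, 2, 7}, {0, 2, 3, 7}, {0, 3, 1, 7}};
  static const double cxyz[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};
  double area = 0.0;
  double val[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + (c & 1), jj = j + ((c >> 1) & 1), kk = k + ((c >> 2) & 1);
          val[c] = field[sub2ind(ii, jj, kk, nx, ny)];
          if (val[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int *tc = tets[t];
          bool in[4];
          int nin = 0;
          for (int m = 0; m < 4; ++m) {
            in[m] = val[tc[m]] > level;
            if (in[m]) ++nin;
          }
          if (nin == 0 || nin == 4) continue;
          // collect crossing points on edges between in/out vertices
          double pts[4][3];
          int np = 0;
          static const int ted[6][2] = {{0,1},{0,2},{0,3},{1,2},{1,3},{2,3}};
          int order22[4];  // records (in-vertex, out-vertex) pairing for quads
          for (int e = 0; e < 6; ++e) {
            int a = ted[e][0], b = ted[e][1];
            if (in[a] == in[b]) continue;
            double va = val[tc[a]], vb = val[tc[b]];
            double tt = (level - va) / (vb - va);
            for (int d = 0; d < 3; ++d)
              pts[np][d] = cxyz[tc[a]][d] + tt * (cxyz[tc[b]][d] - cxyz[tc[a]][d]);
            order22[np] = a * 4 + b;
            ++np;
          }
          if (nin == 1 || nin == 3) {
            area += tri_area(pts[0], pts[1], pts[2]);
          } else {
            // quad: order points so consecutive ones share a tet vertex
            // edges crossed are {a,c},{a,d},{b,c},{b,d} with in={a,b}.
            // find the two in-vertices
            int ia = -1, ib = -1;
            for (int m = 0; m < 4; ++m) {
              if (in[m]) { if (ia < 0) ia = m; else ib = m; }
            }
            // perimeter order: (ia,oc1) (ia,oc2) (ib,oc2) (ib,oc1)
            int oc[2], no = 0;
            for (int m = 0; m < 4; ++m) if (!in[m]) oc[no++] = m;
            auto find_pt = [&](int a, int b) {
              int key1 = a * 4 + b, key2 = b * 4 + a;
              for (int m = 0; m < 4; ++m)
                if (order22[m] == key1 || order22[m] == key2) return m;
              return 0;
            };
            int q0 = find_pt(ia, oc[0]), q1 = find_pt(ia, oc[1]),
                q2 = find_pt(ib, oc[1]), q3 = find_pt(ib, oc[0]);
            area += tri_area(pts[q0], pts[q1], pts[q2]);
            area += tri_area(pts[q0], pts[q2], pts[q3]);
          }
        }
      }
  return area;
}
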