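// 3D morphology primitives: homotopic thinning (skeletonization),
// 26-connected component labelling, and tube voxelization by exact
// point-to-segment distance. Volumes are passed as logical/integer vectors in
// R array order (first index fastest) with explicit dims.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int vidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// offset index o = (di+1) + 3*(dj+1) + 9*(dk+1); center is 13
static const int OX[27] = {-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1,-1,0,1};
static const int OY[27] = {-1,-1,-1,0,0,0,1,1,1,-1,-1,-1,0,0,0,1,1,1,-1,-1,-1,0,0,0,1,1,1};
static const int OZ[27] = {-1,-1,-1,-1,-1,-1,-1,-1,-1,0,0,0,0,0,0,0,0,0,1,1,1,1,1,1,1,1,1};

static inline int cheb(int a, int b) {
  int d = 0;
  int dx = std::abs(OX[a] - OX[b]); if (dx > d) d = dx;
  int dy = std::abs(OY[a] - OY[b]); if (dy > d) d = dy;
  int dz = std::abs(OZ[a] - OZ[b]); if (dz > d) d = dz;
  return d;
}

static inline int manh(int a, int b) {
  return std::abs(OX[a] - OX[b]) + std::abs(OY[a] - OY[b]) + std::abs(OZ[a] - OZ[b]);
}

static inline int manh0(int a) {
  return std::abs(OX[a]) + std::abs(OY[a]) + std::abs(OZ[a]);
}

// Gather the 3x3x3 neighbourhood of p; out-of-volume treated as background.
static void gather27(const std::vector<unsigned char>& V, int i, int j, int k,
                     int nx, int ny, int nz, bool fg[27]) {
  for (int o = 0; o < 27; ++o) {
    int ii = i + OX[o], jj = j + OY[o], kk = k + OZ[o];
    fg[o] = (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz) &&
            V[vidx(ii, jj, kk, nx, ny)] != 0;
  }
}

static int count_fg26(const bool fg[27]) {
  int n = 0;
  for (int o = 0; o < 27; ++o) if (o != 13 && fg[o]) ++n;
  return n;
}

// Simple-point characterization (topology preserved on deletion):
//  (a) exactly one 26-connected foreground component in N26(p);
//  (b) exactly one 6-connected background component in N18(p) that is
//      6-adjacent to p.
static bool simple_point(const bool fg[27]) {
  // (a) foreground components, 26-connectivity over the 26 neighbours
  int comp[27]; for (int o = 0; o < 27; ++o) comp[o] = -1;
  int ncomp = 0;
  for (int o = 0; o < 27; ++o) {
    if (o == 13 || !fg[o] || comp[o] >= 0) continue;
    // BFS
    std::vector<int> stack; stack.push_back(o); comp[o] = ncomp;
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      for (int b = 0; b < 27; ++b) {
        if (b == 13 || !fg[b] || comp[b] >= 0) continue;
        if (cheb(a, b) <= 1) { comp[b] = ncomp; stack.push_back(b); }
      }
    }
    ++ncomp;
  }
  if (ncomp != 1) return false;

  // (b) background components in N18, 6-connectivity, touching a face of p
  int bcomp[27]; for (int o = 0; o < 27; ++o) bcomp[o] = -1;
  int nb = 0;
  for (int o = 0; o < 27; ++o) {
    int m = manh0(o);
    if (o == 13 || m > 2 || fg[o] || bcomp[o] >= 0) continue;  // N18 background only
    bool touches_face = (m == 1);
    std::vector<int> stack; stack.push_back(o); bcomp[o] = nb;
    while (!stack.empty()) {
      int a = stack.back(); stack.pop_back();
      for (int b = 0; b < 27; ++b) {
        int mb = manh0(b);
        if (b == 13 || mb > 2 || fg[b] || bcomp[b] >= 0) continue;
        if (manh(a, b) == 1) {
          bcomp[b] = nb; if (mb == 1) touches_face = true;
          stack.push_back(b);
        }
      }
    }
    if (touches_face) ++nb;
  }
  return nb == 1;
}

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<unsigned char> V(n);
  for (R_xlen_t t = 0; t < n; ++t) V[t] = mask[t] == TRUE ? 1 : 0;

  bool fg[27];
  bool changed = true;
  std::vector<int> border;
  while (changed) {
    changed = false;
    border.clear();
    // collect voxels that are border (have a 6-background neighbour) now
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          int t = vidx(i, j, k, nx, ny);
          if (!V[t]) continue;
          bool isborder = false;
          for (int o = 0; o < 27 && !isborder; ++o)
            if (manh0(o) == 1) {
              int ii = i + OX[o], jj = j + OY[o], kk = k + OZ[o];
              bool f = (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz) &&
                       V[vidx(ii, jj, kk, nx, ny)];
              if (!f) isborder = true;
            }
          if (isborder) border.push_back(t);
        }
    // sequential deletion within the pass keeps topology exact
    for (size_t b = 0; b < border.size(); ++b) {
      int t = border[b];
      if (!V[t]) continue;
      int k = t / (nx * ny), r = t % (nx * ny), j = r / nx, i = r % nx;
      gather27(V, i, j, k, nx, ny, nz, fg);
      int nnb = count_fg26(fg);
      if (nnb <= 1) continue;            // endpoints and isolated voxels survive
      if (simple_point(fg)) { V[t] = 0; changed = true; }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t t = 0; t < n; ++t) out[t] = V[t] != 0;
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".label3d_cpp")]]
IntegerVector label3d_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector lab(n, 0);
  int current = 0;
  std::vector<int> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] != TRUE || lab[s] != 0) continue;
    ++current;
    stack.clear(); stack.push_back((int)s); lab[s] = current;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      int k = t / (nx * ny), r = t % (nx * ny), j = r / nx, i = r % nx;
      for (int o = 0; o < 27; ++o) {
        if (o == 13) continue;
        int ii = i + OX[o], jj = j + OY[o], kk = k + OZ[o];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        int u = vidx(ii, jj, kk, nx, ny);
        if (mask[u] == TRUE && lab[u] == 0) { lab[u] = current; stack.push_back(u); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Voxelize a tube of given radius around a polyline. pts is m x 3 (world mm),
// affine maps 0-based voxel indices to world, lo/hi are 0-based inclusive
// index bounds of the candidate box.
// [[Rcpp::export(name = ".tube_mask_cpp")]]
LogicalVector tube_mask_cpp(NumericMatrix pts, double radius, NumericMatrix affine,
                            IntegerVector dims, IntegerVector lo, IntegerVector hi) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n, false);
  out.attr("dim") = dims;
  int m = pts.nrow();
  if (m < 2) stop("need at least two curve points");
  double r2 = radius * radius;
  int nseg = m - 1;
  std::vector<double> ax(nseg), ay(nseg), az(nseg), dx(nseg), dy(nseg), dz(nseg), dd(nseg);
  for (int s = 0; s < nseg; ++s) {
    ax[s] = pts(s, 0); ay[s] = pts(s, 1); az[s] = pts(s, 2);
    dx[s] = pts(s + 1, 0) - ax[s];
    dy[s] = pts(s + 1, 1) - ay[s];
    dz[s] = pts(s + 1, 2) - az[s];
    dd[s] = dx[s] * dx[s] + dy[s] * dy[s] + dz[s] * dz[s];
  }
  for (int k = std::max(0, lo[2]); k <= std::min(nz - 1, hi[2]); ++k)
    for (int j = std::max(0, lo[1]); j <= std::min(ny - 1, hi[1]); ++j)
      for (int i = std::max(0, lo[0]); i <= std::min(nx - 1, hi[0]); ++i) {
        double wx = affine(0, 0) * i + affine(0, 1) * j + affine(0, 2) * k + affine(0, 3);
        double wy = affine(1, 0) * i + affine(1, 1) * j + affine(1, 2) * k + affine(1, 3);
        double wz = affine(2, 0) * i + affine(2, 1) * j + affine(2, 2) * k + affine(2, 3);
        bool hit = false;
        for (int s = 0; s < nseg && !hit; ++s) {
          double px = wx - ax[s], py = wy - ay[s], pz = wz - az[s];
          double t = 0.0;
          if (dd[s] > 0) {
            t = (px * dx[s] + py * dy[s] + pz * dz[s]) / dd[s];
            if (t < 0) t = 0; else if (t > 1) t = 1;
          }
          double qx = px - t * dx[s], qy = py - t * dy[s], qz = pz - t * dz[s];
          if (qx * qx + qy * qy + qz * qz <= r2) hit = true;
        }
        if (hit) out[vidx(i, j, k, nx, ny)] = true;
      }
  return out;
}

// Accumulate projected material depth per raster pixel: for every voxel cell
// whose shadow covers a pixel center, the chord length of the ray from that
// pixel center along the plane normal through the cell is added. uv: n x 2
// in-plane coordinates of voxel centers; s: n offsets along the normal;
// Bu, Bv, Nn: the in-plane basis vectors and normal mapped through the
// inverse voxel-edge matrix (so the cell is the unit box |alpha_i| <= 1/2);
// hu, hv: conservative half-extents of the shadow along u and v.
// [[Rcpp::export(name = ".depth_raster_cpp")]]
NumericMatrix depth_raster_cpp(NumericMatrix uv, NumericVector s,
                               NumericVector Bu, NumericVector Bv,
                               NumericVector Nn, double u0, double v0,
                               double px, int nu, int nv,
                               double hu, double hv) {
  NumericMatrix out(nu, nv);
  int n = uv.nrow();
  for (int t = 0; t < n; ++t) {
    double u = uv(t, 0), v = uv(t, 1), sn = s[t];
    int imin = (int)std::ceil((u - hu - u0) / px);
    int imax = (int)std::floor((u + hu - u0) / px);
    int jmin = (int)std::ceil((v - hv - v0) / px);
    int jmax = (int)std::floor((v + hv - v0) / px);
    if (imin < 0) imin = 0; if (imax > nu - 1) imax = nu - 1;
    if (jmin < 0) jmin = 0; if (jmax > nv - 1) jmax = nv - 1;
    for (int i = imin; i <= imax; ++i) {
      double du = u0 + i * px - u;
      for (int j = jmin; j <= jmax; ++j) {
        double dv = v0 + j * px - v;
        // alpha(tt) = a + tt * Nn must stay in |alpha_k| <= 1/2 over [tlo, thi]
        double tlo = -1e300, thi = 1e300;
        bool ok = true;
        for (int k = 0; k < 3 && ok; ++k) {
          double a = du * Bu[k] + dv * Bv[k] - sn * Nn[k];
          double b = Nn[k];
          if (std::fabs(b) < 1e-12) {
            if (std::fabs(a) > 0.5) ok = false;
          } else {
            double t1 = (-0.5 - a) / b, t2 = (0.5 - a) / b;
            if (t1 > t2) std::swap(t1, t2);
            if (t1 > tlo) tlo = t1;
            if (t2 < thi) thi = t2;
            if (tlo > thi) ok = false;
          }
        }
        if (ok && thi > tlo) out(i, j) += thi - tlo;
      }
    }
  }
  return out;
}
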