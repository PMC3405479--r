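#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Volumes are passed as flat numeric vectors in R's column-major array
// layout: linear index = i + nx*(j + ny*k), all voxel indices 0-based.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear interpolation at continuous 0-based voxel coordinates.
// Out-of-grid points clamp to the border voxel (no background value is
// invented at the edge).
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dims,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double x = clampd(pts(p, 0), 0.0, nx - 1.0);
    double y = clampd(pts(p, 1), 0.0, ny - 1.0);
    double z = clampd(pts(p, 2), 0.0, nz - 1.0);
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
    if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
    if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
    int i1 = std::min(i0 + 1, nx - 1), j1 = std::min(j0 + 1, ny - 1),
        k1 = std::min(k0 + 1, nz - 1);
    double fx = x - i0, fy = y - j0, fz = z - k0;
    const double *v = REAL(vol);
    const R_xlen_t sxy = (R_xlen_t)nx * ny;
#define V(i, j, k) v[(i) + (R_xlen_t)nx * (j) + sxy * (k)]
    double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[p] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Separable truncated-Gaussian smoothing; sigma per axis in voxels,
// truncation radius ceil(3*sigma). The kernel is renormalized over the
// in-bounds taps at each position, so constants are preserved exactly at
// the borders.
// [[Rcpp::export]]
NumericVector cpp_gauss3(NumericVector vol, IntegerVector dims,
                         NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> cur(REAL(vol), REAL(vol) + ntot), nxt(ntot);
  const int n_ax[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    std::vector<double> w(2 * r + 1);
    for (int t = -r; t <= r; ++t)
      w[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
    const int na = n_ax[ax];
    const R_xlen_t sa = stride[ax];
    // iterate over all lines along axis ax
    const int nb = n_ax[(ax + 1) % 3], nc = n_ax[(ax + 2) % 3];
    const R_xlen_t sb = stride[(ax + 1) % 3], sc = stride[(ax + 2) % 3];
    for (int c = 0; c < nc; ++c) {
      for (int b = 0; b < nb; ++b) {
        R_xlen_t base = b * sb + c * sc;
        for (int i = 0; i < na; ++i) {
          int t0 = std::max(-r, -i), t1 = std::min(r, na - 1 - i);
          double acc = 0.0, wsum = 0.0;
          for (int t = t0; t <= t1; ++t) {
            double wt = w[t + r];
            acc += wt * cur[base + (R_xlen_t)(i + t) * sa];
            wsum += wt;
          }
          nxt[base + (R_xlen_t)i * sa] = acc / wsum;
        }
      }
    }
    cur.swap(nxt);
  }
  return NumericVector(cur.begin(), cur.end());
}

// Exhaustive zero-mean NCC search used by salient-feature matching.
// centers: N x 3 integer voxel indices on the source grid (0-based);
// hw: N x 3 window half-widths (voxels); srange: max |displacement| per
// axis in voxels. Both volumes share dims. Returns N x 5:
// (dx, dy, dz) best displacement in (sub-)voxels, best correlation, ok
// flag (0 = window left the source grid or no candidate fit the target).
// [[Rcpp::export]]
NumericMatrix cpp_match_search(NumericVector src, NumericVector tgt,
                               IntegerVector dims, IntegerMatrix centers,
                               IntegerMatrix hw, IntegerVector srange,
                               int peak_excl, double second_peak_ratio) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sxy = (R_xlen_t)nx * ny;
  const double *S = REAL(src), *T = REAL(tgt);
  const int N = centers.nrow();
  NumericMatrix out(N, 5);
  const int rx = srange[0], ry = srange[1], rz = srange[2];
  const int ndx = 2 * rx + 1, ndy = 2 * ry + 1, ndz = 2 * rz + 1;
  std::vector<double> score((size_t)ndx * ndy * ndz);
  std::vector<double> win;
  for (int f = 0; f < N; ++f) {
    const int ci = centers(f, 0), cj = centers(f, 1), ck = centers(f, 2);
    const int hx = hw(f, 0), hy = hw(f, 1), hz = hw(f, 2);
    out(f, 4) = 0.0;
    if (ci - hx < 0 || ci + hx >= nx || cj - hy < 0 || cj + hy >= ny ||
        ck - hz < 0 || ck + hz >= nz)
      continue; // window leaves the source grid: feature discarded
    const R_xlen_t wn = (R_xlen_t)(2 * hx + 1) * (2 * hy + 1) * (2 * hz + 1);
    win.resize(wn);
    double smean = 0.0;
    {
      R_xlen_t q = 0;
      for (int k = ck - hz; k <= ck + hz; ++k)
        for (int j = cj - hy; j <= cj + hy; ++j)
          for (int i = ci - hx; i <= ci + hx; ++i) {
            double v = S[i + (R_xlen_t)nx * j + sxy * k];
            win[q++] = v;
            smean += v;
          }
      smean /= (double)wn;
    }
    double svar = 0.0;
    for (R_xlen_t q = 0; q < wn; ++q) {
      win[q] -= smean;
      svar += win[q] * win[q];
    }
    if (svar <= 0) continue; // flat window cannot be matched
    double best = -2.0;
    int bdx = 0, bdy = 0, bdz = 0;
    std::fill(score.begin(), score.end(), -2.0);
    for (int dz = -rz; dz <= rz; ++dz) {
      int k0 = ck + dz;
      if (k0 - hz < 0 || k0 + hz >= nz) continue;
      for (int dy = -ry; dy <= ry; ++dy) {
        int j0 = cj + dy;
        if (j0 - hy < 0 || j0 + hy >= ny) continue;
        for (int dx = -rx; dx <= rx; ++dx) {
          int i0 = ci + dx;
          if (i0 - hx < 0 || i0 + hx >= nx) continue;
          double tm = 0.0;
          R_xlen_t q = 0;
          double dot = 0.0, tv = 0.0;
          // first pass for the target mean
          for (int k = k0 - hz; k <= k0 + hz; ++k)
            for (int j = j0 - hy; j <= j0 + hy; ++j) {
              const double *row = T + (R_xlen_t)nx * j + sxy * k;
              for (int i = i0 - hx; i <= i0 + hx; ++i) tm += row[i];
            }
          tm /= (double)wn;
          for (int k = k0 - hz; k <= k0 + hz; ++k)
            for (int j = j0 - hy; j <= j0 + hy; ++j) {
              const double *row = T + (R_xlen_t)nx * j + sxy * k;
              for (int i = i0 - hx; i <= i0 + hx; ++i) {
                double tvv = row[i] - tm;
                dot += win[q++] * tvv;
                tv += tvv * tvv;
              }
            }
          double ncc = (tv > 0) ? dot / std::sqrt(svar * tv) : -2.0;
          score[(size_t)(dx + rx) +
                (size_t)ndx * ((size_t)(dy + ry) +
                               (size_t)ndy * (size_t)(dz + rz))] = ncc;
          // prefer the smaller displacement on near-ties (deterministic,
          // avoids sliding along self-similar structures)
          double d2 = (double)dx * dx + (double)dy * dy + (double)dz * dz;
          double b2 = (double)bdx * bdx + (double)bdy * bdy +
                      (double)bdz * bdz;
          if (ncc > best + 1e-9 || (ncc > best - 1e-9 && d2 < b2)) {
            best = ncc;
            bdx = dx; bdy = dy; bdz = dz;
          }
        }
      }
    }
    if (best < -1.5) continue; // no candidate displacement was in bounds
    // distinctiveness: a second correlation peak of comparable height away
    // from the best displacement marks an ambiguous (self-similar) match
    if (second_peak_ratio < 1.0) {
      double best2 = -2.0;
      for (int dz = -rz; dz <= rz; ++dz)
        for (int dy = -ry; dy <= ry; ++dy)
          for (int dx = -rx; dx <= rx; ++dx) {
            if (std::abs(dx - bdx) <= peak_excl &&
                std::abs(dy - bdy) <= peak_excl &&
                std::abs(dz - bdz) <= peak_excl)
              continue;
            double s = score[(size_t)(dx + rx) +
                             (size_t)ndx * ((size_t)(dy + ry) +
                                            (size_t)ndy * (size_t)(dz + rz))];
            if (s > best2) best2 = s;
          }
      if (best2 > second_peak_ratio * best) continue; // discarded
    }
    // quadratic sub-voxel refinement along each axis independently; a
    // perfect correlation (NCC = 1) is already the global optimum of the
    // bounded NCC surface, so it is never shifted
    double sub[3] = {0, 0, 0};
    bool refine = best < 1.0 - 1e-9;
    const int bb[3] = {bdx + rx, bdy + ry, bdz + rz};
    const int nd[3] = {ndx, ndy, ndz};
    const size_t st[3] = {1, (size_t)ndx, (size_t)ndx * ndy};
    size_t bidx = (size_t)bb[0] + st[1] * bb[1] + st[2] * bb[2];
    for (int a = 0; refine && a < 3; ++a) {
      if (bb[a] <= 0 || bb[a] >= nd[a] - 1) continue;
      double fm = score[bidx - st[a]], f0 = score[bidx],
             fp = score[bidx + st[a]];
      if (fm < -1.5 || fp < -1.5) continue;
      double den = fm - 2.0 * f0 + fp;
      if (std::fabs(den) < 1e-12) continue;
      sub[a] = clampd(0.5 * (fm - fp) / den, -0.5, 0.5);
    }
    out(f, 0) = bdx + sub[0];
    out(f, 1) = bdy + sub[1];
    out(f, 2) = bdz + sub[2];
    out(f, 3) = best;
    out(f, 4) = 1.0;
  }
  return out;
}

// Ray-parity point-in-surface rasterization. Rays run along +x through the
// voxel centers of each (j,k) row; a crossing at or before (within tol of)
// the voxel centre counts, so boundary hits land inside. Ray (y,z)
// positions are nudged by a tiny deterministic offset so rays never pass
// exactly through mesh vertices or edges.
// [[Rcpp::export]]
LogicalVector cpp_rasterize(NumericMatrix verts, IntegerMatrix tris,
                            IntegerVector dims, NumericVector spacing,
                            NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int nt = tris.nrow();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  // distinct irrational-looking nudge fractions so rays are never parallel
  // to, nor incident on, lattice edges or the uniform quad diagonals
  const double eps_y = 2.41e-4 * sy, eps_z = 6.18e-4 * sz, tol = 1e-9;
  // per-triangle (y,z) bounding boxes for the row loop
  std::vector<double> ylo(nt), yhi(nt), zlo(nt), zhi(nt);
  for (int t = 0; t < nt; ++t) {
    double y0 = verts(tris(t, 0), 1), y1 = verts(tris(t, 1), 1),
           y2 = verts(tris(t, 2), 1);
    double z0 = verts(tris(t, 0), 2), z1 = verts(tris(t, 1), 2),
           z2 = verts(tris(t, 2), 2);
    ylo[t] = std::min(y0, std::min(y1, y2));
    yhi[t] = std::max(y0, std::max(y1, y2));
    zlo[t] = std::min(z0, std::min(z1, z2));
    zhi[t] = std::max(z0, std::max(z1, z2));
  }
  std::vector<double> cross;
  for (int k = 0; k < nz; ++k) {
    double zr = oz + k * sz + eps_z;
    for (int j = 0; j < ny; ++j) {
      double yr = oy + j * sy + eps_y;
      cross.clear();
      for (int t = 0; t < nt; ++t) {
        if (yr < ylo[t] || yr > yhi[t] || zr < zlo[t] || zr > zhi[t])
          continue;
        const double *v0 = &verts(tris(t, 0), 0);
        // barycentric solve in the (y,z) projection
        double y0 = verts(tris(t, 0), 1), z0 = verts(tris(t, 0), 2);
        double e1y = verts(tris(t, 1), 1) - y0,
               e1z = verts(tris(t, 1), 2) - z0;
        double e2y = verts(tris(t, 2), 1) - y0,
               e2z = verts(tris(t, 2), 2) - z0;
        double det = e1y * e2z - e1z * e2y;
        if (std::fabs(det) < 1e-14) continue; // edge-on to the ray bundle
        double py = yr - y0, pz = zr - z0;
        double u = (py * e2z - pz * e2y) / det;
        double w = (e1y * pz - e1z * py) / det;
        if (u < 0 || w < 0 || u + w > 1) continue;
        double x0 = verts(tris(t, 0), 0);
        double xint = x0 + u * (verts(tris(t, 1), 0) - x0) +
                      w * (verts(tris(t, 2), 0) - x0);
        (void)v0;
        cross.push_back(xint);
      }
      if (cross.empty()) continue;
      std::sort(cross.begin(), cross.end());
      size_t p = 0;
      R_xlen_t base = (R_xlen_t)nx * j + (R_xlen_t)nx * ny * k;
      for (int i = 0; i < nx; ++i) {
        double xc = ox + i * sx;
        while (p < cross.size() && cross[p] <= xc + tol) ++p;
        out[base + i] = (p % 2) == 1;
      }
    }
  }
  return out;
}
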