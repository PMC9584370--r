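#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Marching tetrahedra over a Kuhn (6-tetrahedron) cube decomposition.
//
// The binary mask holds node samples on the voxel-center lattice; the surface
// is the 0.5 iso-level.  A Kuhn decomposition uses the same main diagonal in
// every cube, so face diagonals agree between neighbouring cubes and the
// extracted surface is a closed 2-manifold for any binary input (each edge is
// shared by exactly two triangles).  Tetrahedron cases (1 vs 3, 2 vs 2 nodes
// inside) are unambiguous, unlike marching-cubes face saddles.
// ---------------------------------------------------------------------------

namespace {

struct MeshBuilder {
  std::unordered_map<uint64_t, int> vert_id;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  int edge_vertex(uint64_t ka, uint64_t kb,
                  double ax, double ay, double az,
                  double bx, double by, double bz) {
    uint64_t key = (ka < kb) ? (ka << 32 | kb) : (kb << 32 | ka);
    auto it = vert_id.find(key);
    if (it != vert_id.end()) return it->second;
    int id = (int)vx.size();
    vert_id.emplace(key, id);
    vx.push_back(0.5 * (ax + bx));
    vy.push_back(0.5 * (ay + by));
    vz.push_back(0.5 * (az + bz));
    return id;
  }

  // add triangle (a,b,c), flipping so the normal points along 'out'
  void tri(int a, int b, int c,
           double ox, double oy, double oz) {
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nx = uy * wz - uz * wy;
    double ny = uz * wx - ux * wz;
    double nz = ux * wy - uy * wx;
    if (nx * ox + ny * oy + nz * oz < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  }
};

} // namespace

// [[Rcpp::export(name = ".mt_surface")]]
List mt_surface(LogicalVector mask, IntegerVector dims,
                NumericVector spacing, NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const int* m = LOGICAL(mask);

  auto val = [&](int i, int j, int k) -> int {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0;
    return m[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] ? 1 : 0;
  };
  // node ids on the extended lattice (-1 .. n), used only as hash keys
  const uint64_t NY = ny + 2, NZ = nz + 2;
  auto nid = [&](int i, int j, int k) -> uint64_t {
    return ((uint64_t)(i + 1) * NY + (uint64_t)(j + 1)) * NZ + (uint64_t)(k + 1);
  };

  // the six Kuhn tetrahedra: vertex paths from (0,0,0) to (1,1,1)
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  int tets[6][4][3];
  for (int p = 0; p < 6; ++p) {
    int v[4][3] = {{0,0,0},{0,0,0},{0,0,0},{1,1,1}};
    v[1][perms[p][0]] = 1;
    v[2][perms[p][0]] = 1; v[2][perms[p][1]] = 1;
    for (int a = 0; a < 4; ++a)
      for (int b = 0; b < 3; ++b) tets[p][a][b] = v[a][b];
  }

  MeshBuilder mb;
  for (int i = -1; i < nx; ++i)
  for (int j = -1; j < ny; ++j)
  for (int k = -1; k < nz; ++k) {
    int c[2][2][2], s = 0;
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b)
        for (int d = 0; d < 2; ++d)
          s += (c[a][b][d] = val(i + a, j + b, k + d));
    if (s == 0 || s == 8) continue;

    for (int p = 0; p < 6; ++p) {
      int gi[4], gj[4], gk[4], tv[4], pos = 0;
      for (int a = 0; a < 4; ++a) {
        gi[a] = i + tets[p][a][0];
        gj[a] = j + tets[p][a][1];
        gk[a] = k + tets[p][a][2];
        tv[a] = c[tets[p][a][0]][tets[p][a][1]][tets[p][a][2]];
        pos += tv[a];
      }
      if (pos == 0 || pos == 4) continue;

      double px[4], py[4], pz[4];
      uint64_t id[4];
      for (int a = 0; a < 4; ++a) {
        px[a] = ox + gi[a] * hx;
        py[a] = oy + gj[a] * hy;
        pz[a] = oz + gk[a] * hz;
        id[a] = nid(gi[a], gj[a], gk[a]);
      }
      auto ev = [&](int a, int b) {
        return mb.edge_vertex(id[a], id[b], px[a], py[a], pz[a],
                              px[b], py[b], pz[b]);
      };
      if (pos == 1 || pos == 3) {
        int lone = -1;
        for (int a = 0; a < 4; ++a)
          if ((pos == 1 && tv[a] == 1) || (pos == 3 && tv[a] == 0)) lone = a;
        int o[3], n = 0;
        for (int a = 0; a < 4; ++a) if (a != lone) o[n++] = a;
        int t0 = ev(lone, o[0]), t1 = ev(lone, o[1]), t2 = ev(lone, o[2]);
        double cx = (mb.vx[t0] + mb.vx[t1] + mb.vx[t2]) / 3.0;
        double cy = (mb.vy[t0] + mb.vy[t1] + mb.vy[t2]) / 3.0;
        double cz = (mb.vz[t0] + mb.vz[t1] + mb.vz[t2]) / 3.0;
        // outward = away from the inside vertex
        double dx, dy, dz;
        if (pos == 1) { dx = cx - px[lone]; dy = cy - py[lone]; dz = cz - pz[lone]; }
        else          { dx = px[lone] - cx; dy = py[lone] - cy; dz = pz[lone] - cz; }
        mb.tri(t0, t1, t2, dx, dy, dz);
      } else { // 2 vs 2: quad through the four crossing edges
        int P[2], N[2], np = 0, nn = 0;
        for (int a = 0; a < 4; ++a) (tv[a] ? P[np++] : N[nn++]) = a;
        int q0 = ev(P[0], N[0]), q1 = ev(P[0], N[1]),
            q2 = ev(P[1], N[1]), q3 = ev(P[1], N[0]);
        double dx = 0.5 * (px[N[0]] + px[N[1]]) - 0.5 * (px[P[0]] + px[P[1]]);
        double dy = 0.5 * (py[N[0]] + py[N[1]]) - 0.5 * (py[P[0]] + py[P[1]]);
        double dz = 0.5 * (pz[N[0]] + pz[N[1]]) - 0.5 * (pz[P[0]] + pz[P[1]]);
        mb.tri(q0, q1, q2, dx, dy, dz);
        mb.tri(q0, q2, q3, dx, dy, dz);
      }
    }
  }

  const int nv = (int)mb.vx.size(), nf = (int)mb.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int a = 0; a < nv; ++a) {
    V(a, 0) = mb.vx[a]; V(a, 1) = mb.vy[a]; V(a, 2) = mb.vz[a];
  }
  for (int a = 0; a < nf; ++a) {
    F(a, 0) = mb.f0[a] + 1; F(a, 1) = mb.f1[a] + 1; F(a, 2) = mb.f2[a] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---------------------------------------------------------------------------
// 6-connected component labelling of a binary mask.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const int* m = LOGICAL(mask);
  IntegerVector out(n, 0);
  int* lab = INTEGER(out);
  int cur = 0;
  std::vector<size_t> stack;
  const int di[6] = {1,-1,0,0,0,0}, dj[6] = {0,0,1,-1,0,0}, dk[6] = {0,0,0,0,1,-1};
  for (size_t s = 0; s < n; ++s) {
    if (!m[s] || lab[s]) continue;
    ++cur;
    stack.push_back(s);
    lab[s] = cur;
    while (!stack.empty()) {
      size_t v = stack.back(); stack.pop_back();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((size_t)nx * ny));
      for (int d = 0; d < 6; ++d) {
        int i2 = i + di[d], j2 = j + dj[d], k2 = k + dk[d];
        if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz) continue;
        size_t v2 = (size_t)i2 + (size_t)nx * ((size_t)j2 + (size_t)ny * k2);
        if (m[v2] && !lab[v2]) { lab[v2] = cur; stack.push_back(v2); }
      }
    }
  }
  out.attr("dim") = dims;
  out.attr("n_components") = cur;
  return out;
}

// ---------------------------------------------------------------------------
// Mesh voxelization by z-ray parity.
//
// Voxel centers sit at grid0 + index*res.  Rays are cast along z through each
// (x,y) column center; a tiny irrational jitter on the ray position and a
// +eps nudge on crossing depths resolve ray/edge and surface/center
// coincidences deterministically (voxel-center inside test, unbiased for
// closed surfaces).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".voxelize_rays")]]
List voxelize_rays(NumericMatrix V, IntegerMatrix F, double res,
                   NumericVector grid0, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double g0x = grid0[0], g0y = grid0[1], g0z = grid0[2];
  const double jx = res * 7.071067811865475e-4;   // sqrt(2)/2 * 1e-3
  const double jy = res * 8.660254037844387e-4;   // sqrt(3)/2 * 1e-3
  const double epsz = res * 1e-7;

  std::vector<std::vector<double>> cols((size_t)nx * ny);
  const int nf = F.nrow();
  for (int f = 0; f < nf; ++f) {
    const int a = F(f, 0) - 1, b = F(f, 1) - 1, c = F(f, 2) - 1;
    const double p0x = V(a,0), p0y = V(a,1), p0z = V(a,2);
    const double e1x = V(b,0) - p0x, e1y = V(b,1) - p0y, e1z = V(b,2) - p0z;
    const double e2x = V(c,0) - p0x, e2y = V(c,1) - p0y, e2z = V(c,2) - p0z;
    const double det = e1x * e2y - e2x * e1y;
    const double scale = std::max({std::abs(e1x), std::abs(e1y),
                                   std::abs(e2x), std::abs(e2y), 1e-300});
    if (std::abs(det) < 1e-12 * scale * scale) continue; // parallel to z
    double xmin = std::min({V(a,0), V(b,0), V(c,0)});
    double xmax = std::max({V(a,0), V(b,0), V(c,0)});
    double ymin = std::min({V(a,1), V(b,1), V(c,1)});
    double ymax = std::max({V(a,1), V(b,1), V(c,1)});
    int ilo = (int)std::ceil ((xmin - g0x - jx) / res);
    int ihi = (int)std::floor((xmax - g0x - jx) / res);
    int jlo = (int)std::ceil ((ymin - g0y - jy) / res);
    int jhi = (int)std::floor((ymax - g0y - jy) / res);
    ilo = std::max(ilo, 0); ihi = std::min(ihi, nx - 1);
    jlo = std::max(jlo, 0); jhi = std::min(jhi, ny - 1);
    for (int i = ilo; i <= ihi; ++i) {
      const double ax = g0x + i * res + jx - p0x;
      for (int j = jlo; j <= jhi; ++j) {
        const double ay = g0y + j * res + jy - p0y;
        const double s = (ax * e2y - e2x * ay) / det;
        if (s < 0 || s > 1) continue;
        const double t = (e1x * ay - ax * e1y) / det;
        if (t < 0 || s + t > 1) continue;
        cols[(size_t)i + (size_t)nx * j].push_back(p0z + s * e1z + t * e2z + epsz);
      }
    }
  }

  LogicalVector out((size_t)nx * ny * nz, false);
  int* o = LOGICAL(out);
  int odd_columns = 0;
  for (int j = 0; j < ny; ++j)
  for (int i = 0; i < nx; ++i) {
    std::vector<double>& z = cols[(size_t)i + (size_t)nx * j];
    if (z.empty()) continue;
    std::sort(z.begin(), z.end());
    if (z.size() % 2) ++odd_columns;
    for (size_t p = 0; p + 1 < z.size(); p += 2) {
      int klo = (int)std::floor((z[p]     - g0z) / res) + 1;
      int khi = (int)std::floor((z[p + 1] - g0z) / res);
      klo = std::max(klo, 0); khi = std::min(khi, nz - 1);
      for (int k = klo; k <= khi; ++k)
        o[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)] = true;
    }
  }
  out.attr("dim") = dims;
  return List::create(_["mask"] = out, _["odd_columns"] = odd_columns);
}

// ---------------------------------------------------------------------------
// Gap closure between labelled components.
//
// A background voxel is filled iff (a) its nearest component and the nearest
// *different* component are both within max_gap (Euclidean distance between
// voxel centers, isotropic spacing), and (b) it lies *between* them: the
// displacement vectors to the two nearest distinct components subtend an
// obtuse angle.  (b) distinguishes a sliver of background separating two
// parallel surfaces (a segmentation gap) from background at a corner where
// two components already touch, or inside a genuine hole such as a plate
// fenestration; those are left alone.  Filled voxels take the nearer
// component's label, ties going to the lower label id.  Distances are
// propagated outward from component boundary voxels over a precomputed
// offset ball.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".fill_gaps")]]
IntegerVector fill_gaps(IntegerVector labels, IntegerVector dims,
                        double spacing, double max_gap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = (size_t)nx * ny * nz;
  const int* L = INTEGER(labels);

  // offsets within the max_gap ball (excluding 0)
  const int rad = (int)std::floor(max_gap / spacing + 1e-9);
  std::vector<int> odx, ody, odz;
  std::vector<double> od;
  for (int a = -rad; a <= rad; ++a)
  for (int b = -rad; b <= rad; ++b)
  for (int c = -rad; c <= rad; ++c) {
    if (!a && !b && !c) continue;
    double d = spacing * std::sqrt((double)(a*a + b*b + c*c));
    if (d <= max_gap + 1e-9) {
      odx.push_back(a); ody.push_back(b); odz.push_back(c); od.push_back(d);
    }
  }

  // distinct labels, ascending
  std::vector<int> labs;
  for (size_t s = 0; s < n; ++s)
    if (L[s] > 0 && std::find(labs.begin(), labs.end(), L[s]) == labs.end())
      labs.push_back(L[s]);
  std::sort(labs.begin(), labs.end());

  const double INF = 1e30;
  std::vector<float> d1(n, (float)INF), d2(n, (float)INF), dc(n);
  std::vector<int> l1(n, 0);

  for (int lab : labs) {
    std::fill(dc.begin(), dc.end(), (float)INF);
    // boundary voxels of this component
    for (size_t s = 0; s < n; ++s) {
      if (L[s] != lab) continue;
      int i = (int)(s % nx), j = (int)((s / nx) % ny), k = (int)(s / ((size_t)nx * ny));
      bool boundary = false;
      static const int di[6] = {1,-1,0,0,0,0}, dj[6] = {0,0,1,-1,0,0},
                       dk[6] = {0,0,0,0,1,-1};
      for (int d = 0; d < 6 && !boundary; ++d) {
        int i2 = i + di[d], j2 = j + dj[d], k2 = k + dk[d];
        if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
          boundary = true;
        else if (L[(size_t)i2 + (size_t)nx * ((size_t)j2 + (size_t)ny * k2)] != lab)
          boundary = true;
      }
      if (!boundary) continue;
      for (size_t t = 0; t < odx.size(); ++t) {
        int i2 = i + odx[t], j2 = j + ody[t], k2 = k + odz[t];
        if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz) continue;
        size_t v = (size_t)i2 + (size_t)nx * ((size_t)j2 + (size_t)ny * k2);
        if (L[v] != 0) continue;
        if ((float)od[t] < dc[v]) dc[v] = (float)od[t];
      }
    }
    // merge this component into the running two-nearest record; components
    // are processed in ascending label order, so ties keep the lower label
    for (size_t s = 0; s < n; ++s) {
      if (dc[s] >= INF) continue;
      if (dc[s] < d1[s]) {
        d2[s] = d1[s];
        d1[s] = dc[s];
        l1[s] = lab;
      } else if (dc[s] < d2[s]) {
        d2[s] = dc[s];
      }
    }
  }

  // second pass over the (few) screened candidates: representative
  // displacement to each component = lexicographically smallest offset
  // (dx, dy, dz ascending) among those achieving the minimal distance,
  // making the obtuse-angle test deterministic and oracle-replicable
  IntegerVector out = clone(labels);
  int* O = INTEGER(out);
  int filled = 0;
  const float mg = (float)(max_gap + 1e-9);
  const int maxlab = labs.back();
  std::vector<double> bestd(maxlab + 1);
  std::vector<int> besto(maxlab + 1);
  for (size_t s = 0; s < n; ++s) {
    if (L[s] != 0 || d2[s] > mg) continue;
    const int i = (int)(s % nx), j = (int)((s / nx) % ny),
              k = (int)(s / ((size_t)nx * ny));
    std::fill(bestd.begin(), bestd.end(), INF);
    std::fill(besto.begin(), besto.end(), -1);
    for (size_t t = 0; t < odx.size(); ++t) {
      int i2 = i + odx[t], j2 = j + ody[t], k2 = k + odz[t];
      if (i2 < 0 || j2 < 0 || k2 < 0 || i2 >= nx || j2 >= ny || k2 >= nz)
        continue;
      int lb = L[(size_t)i2 + (size_t)nx * ((size_t)j2 + (size_t)ny * k2)];
      if (lb > 0 && od[t] < bestd[lb] - 1e-12) {
        bestd[lb] = od[t];
        besto[lb] = (int)t;
      }
    }
    int L1 = 0, L2 = 0;
    for (int lb : labs)  // ascending, so distance ties keep the lower label
      if (besto[lb] >= 0 && (L1 == 0 || bestd[lb] < bestd[L1] - 1e-12)) L1 = lb;
    for (int lb : labs)
      if (lb != L1 && besto[lb] >= 0 &&
          (L2 == 0 || bestd[lb] < bestd[L2] - 1e-12)) L2 = lb;
    if (L1 == 0 || L2 == 0 || bestd[L2] > mg) continue;
    const int a = besto[L1], b = besto[L2];
    double dot = (double)odx[a] * odx[b] + (double)ody[a] * ody[b] +
                 (double)odz[a] * odz[b];
    if (dot < -1e-9) { O[s] = L1; ++filled; }
  }
  out.attr("dim") = dims;
  out.attr("n_filled") = filled;
  return out;
}
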