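#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <cstring>
#include <cstdio>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-based RNG: every voxel owns an independent splitmix64 stream keyed
// by (seed, global voxel linear index), so results do not depend on traversal
// order or on which sub-grid a voxel is sampled from.
// ---------------------------------------------------------------------------

static inline uint64_t sm64_next(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t voxel_stream(uint64_t seed, uint64_t gidx) {
  // decorrelate the linear index before xoring into the seed
  uint64_t s = gidx * 0xD1B54A32D192ED03ULL + 0x8CB92BA72F3D8DD7ULL;
  uint64_t st = s;
  uint64_t h = sm64_next(st);
  return seed ^ h;
}

static inline double u01(uint64_t &state) {
  return (sm64_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

// ---------------------------------------------------------------------------
// Precomputed tetrahedron: vertex a plus the inverse of the edge matrix, so a
// point's barycentric coordinates cost three dot products. Tets are assumed
// orientation-normalized (positive signed volume); degenerate tets are
// excluded from sampling (they carry no volume).
// ---------------------------------------------------------------------------

struct TetPre {
  double a[3];
  double r[9];        // rows of inv([b-a | c-a | d-a])
  double lo[3], hi[3];
  double dens;
  int    id;          // position in the caller's tet ordering (tie-break)
  bool   degenerate;
};

static void tet_precompute(const double *n0, const double *n1,
                           const double *n2, const double *n3,
                           double dens, int id, TetPre &t) {
  double e1[3], e2[3], e3[3];
  for (int k = 0; k < 3; ++k) {
    t.a[k] = n0[k];
    e1[k] = n1[k] - n0[k];
    e2[k] = n2[k] - n0[k];
    e3[k] = n3[k] - n0[k];
    t.lo[k] = std::min(std::min(n0[k], n1[k]), std::min(n2[k], n3[k]));
    t.hi[k] = std::max(std::max(n0[k], n1[k]), std::max(n2[k], n3[k]));
  }
  double det =
      e1[0] * (e2[1] * e3[2] - e2[2] * e3[1]) -
      e2[0] * (e1[1] * e3[2] - e1[2] * e3[1]) +
      e3[0] * (e1[1] * e2[2] - e1[2] * e2[1]);
  t.dens = dens;
  t.id = id;
  t.degenerate = (std::fabs(det) < 1e-300);
  if (t.degenerate) { std::memset(t.r, 0, sizeof(t.r)); return; }
  double inv = 1.0 / det;
  // adjugate transpose: rows of the inverse
  t.r[0] = (e2[1] * e3[2] - e2[2] * e3[1]) * inv;
  t.r[1] = (e2[2] * e3[0] - e2[0] * e3[2]) * inv;
  t.r[2] = (e2[0] * e3[1] - e2[1] * e3[0]) * inv;
  t.r[3] = (e1[2] * e3[1] - e1[1] * e3[2]) * inv;
  t.r[4] = (e1[0] * e3[2] - e1[2] * e3[0]) * inv;
  t.r[5] = (e1[1] * e3[0] - e1[0] * e3[1]) * inv;
  t.r[6] = (e1[1] * e2[2] - e1[2] * e2[1]) * inv;
  t.r[7] = (e1[2] * e2[0] - e1[0] * e2[2]) * inv;
  t.r[8] = (e1[0] * e2[1] - e1[1] * e2[0]) * inv;
}

// claim test: all four barycentric coordinates >= -tol (boundary inclusive)
static inline bool tet_claims(const TetPre &t, const double *p, double tol) {
  if (t.degenerate) return false;
  double q0 = p[0] - t.a[0], q1 = p[1] - t.a[1], q2 = p[2] - t.a[2];
  double l2 = t.r[0] * q0 + t.r[1] * q1 + t.r[2] * q2;
  if (l2 < -tol) return false;
  double l3 = t.r[3] * q0 + t.r[4] * q1 + t.r[5] * q2;
  if (l3 < -tol) return false;
  double l4 = t.r[6] * q0 + t.r[7] * q1 + t.r[8] * q2;
  if (l4 < -tol) return false;
  return (1.0 - l2 - l3 - l4) >= -tol;
}

static inline void tet_bary(const TetPre &t, const double *p, double *lam) {
  double q0 = p[0] - t.a[0], q1 = p[1] - t.a[1], q2 = p[2] - t.a[2];
  lam[1] = t.r[0] * q0 + t.r[1] * q1 + t.r[2] * q2;
  lam[2] = t.r[3] * q0 + t.r[4] * q1 + t.r[5] * q2;
  lam[3] = t.r[6] * q0 + t.r[7] * q1 + t.r[8] * q2;
  lam[0] = 1.0 - lam[1] - lam[2] - lam[3];
}

// ---------------------------------------------------------------------------
// Exact interior shortcut.  If the lowest-indexed candidate that contains all
// eight voxel corners (barycentric >= -tol) is either the first candidate or
// every earlier candidate is separated from the voxel by one of its own
// barycentric planes (all corners < -tol on that plane), then, because
// barycentric coordinates are affine and attain their extrema at the corners,
// every sample point would be claimed by that candidate: w = 1 exactly.  The
// shortcut is therefore bit-identical to drawing the points.
// ---------------------------------------------------------------------------

static inline void voxel_corners(const double *vlo, const double *vhi,
                                 double c[8][3]) {
  for (int i = 0; i < 8; ++i) {
    c[i][0] = (i & 1) ? vhi[0] : vlo[0];
    c[i][1] = (i & 2) ? vhi[1] : vlo[1];
    c[i][2] = (i & 4) ? vhi[2] : vlo[2];
  }
}

static bool contains_all_corners(const TetPre &t, double c[8][3], double tol) {
  if (t.degenerate) return false;
  for (int i = 0; i < 8; ++i)
    if (!tet_claims(t, c[i], tol)) return false;
  return true;
}

static bool plane_separates(const TetPre &t, double c[8][3], double tol) {
  if (t.degenerate) return true;
  double lam[8][4];
  for (int i = 0; i < 8; ++i) tet_bary(t, c[i], lam[i]);
  for (int f = 0; f < 4; ++f) {
    bool sep = true;
    for (int i = 0; i < 8; ++i)
      if (lam[i][f] >= -tol) { sep = false; break; }
    if (sep) return true;
  }
  return false;
}

// Sample one voxel: fills cnt (per candidate, caller order) and returns the
// number of claimed points.  Candidates must be in ascending tie-break order.
static long sample_points(const std::vector<const TetPre *> &cand,
                          const double *vlo, const double *sp,
                          long N, uint64_t state, double tol,
                          std::vector<long> &cnt) {
  long claimed = 0;
  double p[3];
  const size_t nc = cand.size();
  for (long k = 0; k < N; ++k) {
    p[0] = vlo[0] + u01(state) * sp[0];
    p[1] = vlo[1] + u01(state) * sp[1];
    p[2] = vlo[2] + u01(state) * sp[2];
    for (size_t j = 0; j < nc; ++j) {
      if (tet_claims(*cand[j], p, tol)) { ++cnt[j]; ++claimed; break; }
    }
  }
  return claimed;
}

// shortcut attempt: returns index into cand of the tet that takes w = 1, or
// -1 if sampling is required.
static int interior_shortcut(const std::vector<const TetPre *> &cand,
                             const double *vlo, const double *vhi,
                             double tol) {
  double c[8][3];
  voxel_corners(vlo, vhi, c);
  int J = -1;
  for (size_t j = 0; j < cand.size(); ++j) {
    if (contains_all_corners(*cand[j], c, tol)) { J = (int)j; break; }
  }
  if (J < 0) return -1;
  for (int j = 0; j < J; ++j)
    if (!plane_separates(*cand[j], c, tol)) return -1;
  return J;
}

// ---------------------------------------------------------------------------
// Uniform spatial bin index over tet AABBs (acceleration structure).
// ---------------------------------------------------------------------------

struct BinIndex {
  double lo[3], cell[3];
  int nc[3];
  std::vector<std::vector<int> > bins;   // tet indices, ascending

  void build(const std::vector<TetPre> &tets,
             const double *rlo, const double *rhi) {
    double mean_ext[3] = {0, 0, 0};
    size_t nt = tets.size();
    for (size_t i = 0; i < nt; ++i)
      for (int k = 0; k < 3; ++k) mean_ext[k] += tets[i].hi[k] - tets[i].lo[k];
    for (int k = 0; k < 3; ++k) {
      lo[k] = rlo[k];
      double ext = rhi[k] - rlo[k];
      double target = nt ? std::max(mean_ext[k] / nt, ext / 256.0) : ext;
      if (target <= 0) target = 1.0;
      nc[k] = std::max(1, std::min(256, (int)std::ceil(ext / target)));
      cell[k] = ext > 0 ? ext / nc[k] : 1.0;
    }
    bins.assign((size_t)nc[0] * nc[1] * nc[2], std::vector<int>());
    for (size_t i = 0; i < nt; ++i) {
      int clo[3], chi[3];
      bool out = false;
      for (int k = 0; k < 3; ++k) {
        clo[k] = (int)std::floor((tets[i].lo[k] - lo[k]) / cell[k]);
        chi[k] = (int)std::floor((tets[i].hi[k] - lo[k]) / cell[k]);
        if (chi[k] < 0 || clo[k] >= nc[k]) { out = true; break; }
        clo[k] = std::max(clo[k], 0);
        chi[k] = std::min(chi[k], nc[k] - 1);
      }
      if (out) continue;
      for (int cz = clo[2]; cz <= chi[2]; ++cz)
        for (int cy = clo[1]; cy <= chi[1]; ++cy)
          for (int cx = clo[0]; cx <= chi[0]; ++cx)
            bins[(size_t)cx + (size_t)nc[0] * (cy + (size_t)nc[1] * cz)]
                .push_back((int)i);
    }
  }

  void gather(const double *vlo, const double *vhi,
              std::vector<int> &out) const {
    int clo[3], chi[3];
    for (int k = 0; k < 3; ++k) {
      clo[k] = std::max(0, (int)std::floor((vlo[k] - lo[k]) / cell[k]));
      chi[k] = std::min(nc[k] - 1, (int)std::floor((vhi[k] - lo[k]) / cell[k]));
      if (chi[k] < clo[k]) { out.clear(); return; }
    }
    out.clear();
    for (int cz = clo[2]; cz <= chi[2]; ++cz)
      for (int cy = clo[1]; cy <= chi[1]; ++cy)
        for (int cx = clo[0]; cx <= chi[0]; ++cx) {
          const std::vector<int> &b =
              bins[(size_t)cx + (size_t)nc[0] * (cy + (size_t)nc[1] * cz)];
          out.insert(out.end(), b.begin(), b.end());
        }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  }
};

static inline bool aabb_overlap(const TetPre &t, const double *vlo,
                                const double *vhi, double eps) {
  for (int k = 0; k < 3; ++k)
    if (t.hi[k] + eps < vlo[k] || t.lo[k] - eps > vhi[k]) return false;
  return true;
}

static std::vector<TetPre> precompute_all(const NumericMatrix &nodes,
                                          const IntegerMatrix &tets,
                                          const NumericVector &dens) {
  int m = tets.nrow();
  std::vector<TetPre> out((size_t)m);
  int n = nodes.nrow();
  std::vector<double> nd((size_t)n * 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) nd[(size_t)i * 3 + k] = nodes(i, k);
  for (int i = 0; i < m; ++i) {
    int a = tets(i, 0) - 1, b = tets(i, 1) - 1,
        c = tets(i, 2) - 1, d = tets(i, 3) - 1;
    tet_precompute(&nd[(size_t)a * 3], &nd[(size_t)b * 3],
                   &nd[(size_t)c * 3], &nd[(size_t)d * 3],
                   dens[i], i, out[(size_t)i]);
  }
  return out;
}

// [[Rcpp::export(name = ".voxelize_kernel")]]
List voxelize_kernel(NumericMatrix nodes, IntegerMatrix tets,
                     NumericVector tet_density,
                     NumericVector origin, NumericVector spacing,
                     IntegerVector dims,
                     IntegerVector sub_lo, IntegerVector sub_hi,
                     double points_per_mm3, double seed, double tol,
                     bool accelerate) {
  std::vector<TetPre> pre = precompute_all(nodes, tets, tet_density);
  const double aabb_eps = 1e-6;   // covers the -tol claim band around a tet

  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  int nx = dims[0], ny = dims[1];
  int lo0 = sub_lo[0], lo1 = sub_lo[1], lo2 = sub_lo[2];
  int hi0 = sub_hi[0], hi1 = sub_hi[1], hi2 = sub_hi[2];
  int snx = hi0 - lo0 + 1, sny = hi1 - lo1 + 1, snz = hi2 - lo2 + 1;
  if (snx <= 0 || sny <= 0 || snz <= 0)
    stop("empty sub-grid");

  NumericVector wsum((R_xlen_t)snx * sny * snz);
  NumericVector wden((R_xlen_t)snx * sny * snz);

  double voxvol = sp[0] * sp[1] * sp[2];
  long N = (long)std::llround(points_per_mm3 * voxvol);
  if (N < 1) N = 1;
  uint64_t seed64 = (uint64_t)(int64_t)std::llround(seed);

  // region AABB (outer faces of the boundary sub-voxels)
  double rlo[3], rhi[3];
  rlo[0] = origin[0] + (lo0 - 0.5) * sp[0];
  rlo[1] = origin[1] + (lo1 - 0.5) * sp[1];
  rlo[2] = origin[2] + (lo2 - 0.5) * sp[2];
  rhi[0] = origin[0] + (hi0 + 0.5) * sp[0];
  rhi[1] = origin[1] + (hi1 + 0.5) * sp[1];
  rhi[2] = origin[2] + (hi2 + 0.5) * sp[2];

  BinIndex index;
  if (accelerate) index.build(pre, rlo, rhi);

  std::vector<int> gathered;
  std::vector<const TetPre *> cand;
  std::vector<long> cnt;
  R_xlen_t out_i = 0;
  long done = 0;

  for (int iz = lo2; iz <= hi2; ++iz) {
    double vz0 = origin[2] + (iz - 0.5) * sp[2];
    for (int iy = lo1; iy <= hi1; ++iy) {
      double vy0 = origin[1] + (iy - 0.5) * sp[1];
      if (((++done) & 255) == 0) Rcpp::checkUserInterrupt();
      for (int ix = lo0; ix <= hi0; ++ix, ++out_i) {
        double vlo[3] = {origin[0] + (ix - 0.5) * sp[0], vy0, vz0};
        double vhi[3] = {vlo[0] + sp[0], vlo[1] + sp[1], vlo[2] + sp[2]};

        cand.clear();
        if (accelerate) {
          index.gather(vlo, vhi, gathered);
          for (size_t j = 0; j < gathered.size(); ++j) {
            const TetPre &t = pre[(size_t)gathered[j]];
            if (aabb_overlap(t, vlo, vhi, aabb_eps)) cand.push_back(&t);
          }
        } else {
          for (size_t j = 0; j < pre.size(); ++j)
            if (aabb_overlap(pre[j], vlo, vhi, aabb_eps))
              cand.push_back(&pre[j]);
        }
        if (cand.empty()) continue;

        int J = interior_shortcut(cand, vlo, vhi, tol);
        if (J >= 0) {
          wsum[out_i] = 1.0;
          wden[out_i] = cand[(size_t)J]->dens;
          continue;
        }

        uint64_t state =
            voxel_stream(seed64, (uint64_t)ix +
                                     (uint64_t)nx * ((uint64_t)iy +
                                                     (uint64_t)ny * (uint64_t)iz));
        cnt.assign(cand.size(), 0L);
        long claimed = sample_points(cand, vlo, sp, N, state, tol, cnt);
        if (claimed == 0) continue;
        double s = 0.0, sd = 0.0;
        for (size_t j = 0; j < cand.size(); ++j) {
          s += (double)cnt[j];
          sd += (double)cnt[j] * cand[j]->dens;
        }
        wsum[out_i] = s / (double)N;
        wden[out_i] = sd / (double)N;
      }
    }
  }

  return List::create(_["wsum"] = wsum, _["wden"] = wden,
                      _["points_per_voxel"] = (double)N);
}

// Per-voxel weights for an explicit candidate list (ascending tie-break
// order as supplied).  Shares every code path with the grid kernel.
// [[Rcpp::export(name = ".sample_voxel_kernel")]]
List sample_voxel_kernel(NumericMatrix nodes, IntegerMatrix tets,
                         NumericVector tet_density,
                         NumericVector voxel_center, NumericVector spacing,
                         double gidx, double points_per_mm3, double seed,
                         double tol, bool shortcut) {
  std::vector<TetPre> pre = precompute_all(nodes, tets, tet_density);
  std::vector<const TetPre *> cand;
  for (size_t j = 0; j < pre.size(); ++j) cand.push_back(&pre[j]);

  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double vlo[3] = {voxel_center[0] - 0.5 * sp[0],
                   voxel_center[1] - 0.5 * sp[1],
                   voxel_center[2] - 0.5 * sp[2]};
  double vhi[3] = {vlo[0] + sp[0], vlo[1] + sp[1], vlo[2] + sp[2]};
  long N = (long)std::llround(points_per_mm3 * sp[0] * sp[1] * sp[2]);
  if (N < 1) N = 1;

  NumericVector w(pre.size());
  if (!cand.empty() && shortcut) {
    int J = interior_shortcut(cand, vlo, vhi, tol);
    if (J >= 0) {
      w[J] = 1.0;
      return List::create(_["w"] = w, _["n_points"] = (double)N,
                          _["sampled"] = false);
    }
  }
  uint64_t seed64 = (uint64_t)(int64_t)std::llround(seed);
  uint64_t state = voxel_stream(seed64, (uint64_t)(int64_t)std::llround(gidx));
  std::vector<long> cnt(cand.size(), 0L);
  if (!cand.empty()) sample_points(cand, vlo, sp, N, state, tol, cnt);
  for (size_t j = 0; j < cand.size(); ++j) w[j] = (double)cnt[j] / (double)N;
  return List::create(_["w"] = w, _["n_points"] = (double)N,
                      _["sampled"] = true);
}

// Boundary-inclusive membership of points in any tet of a mesh.
// [[Rcpp::export(name = ".points_in_mesh")]]
LogicalVector points_in_mesh(NumericMatrix nodes, IntegerMatrix tets,
                             NumericMatrix points, double tol) {
  NumericVector dens(tets.nrow(), 1.0);
  std::vector<TetPre> pre = precompute_all(nodes, tets, dens);
  int np = points.nrow();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    double p[3] = {points(i, 0), points(i, 1), points(i, 2)};
    bool inside = false;
    for (size_t j = 0; j < pre.size() && !inside; ++j) {
      const TetPre &t = pre[j];
      if (p[0] < t.lo[0] - 1e-9 || p[0] > t.hi[0] + 1e-9 ||
          p[1] < t.lo[1] - 1e-9 || p[1] > t.hi[1] + 1e-9 ||
          p[2] < t.lo[2] - 1e-9 || p[2] > t.hi[2] + 1e-9) continue;
      inside = tet_claims(t, p, tol);
    }
    out[i] = inside;
  }
  return out;
}

// [[Rcpp::export(name = ".fnv1a64")]]
String fnv1a64(RawVector bytes) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= 0x100000001B3ULL;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return String(buf);
}
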