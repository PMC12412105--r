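// Dissipative particle dynamics engine for grafted, cross-linkable polymer
// films. Standard soft conservative force a_ij (1 - r/r_c), pairwise
// dissipative/random thermostat obeying fluctuation-dissipation
// (sigma^2 = 2 gamma kT), harmonic bonds, modified velocity-Verlet
// integration (Groot-Warren, parameter lambda). Reduced units r_c = 1,
// m = 1, kT set by the thermostat.
//
// Geometry: periodic in x and y; in z either periodic (bulk fluid tests) or
// bounded by bounce-back walls backed by frozen wall-bead layers. Optional
// frozen spherical-cap obstacles, modeled as y-invariant circular ridges
// (the narrow-box approximation: box width << cap radius, so curvature
// along the width is negligible).

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

struct Cap { double cx, cz, R; };

struct DpdBox {
  double Lx, Ly, Lz;
  bool periodic_z;
  inline double wx(double d) const {
    if (d > 0.5 * Lx) d -= Lx; else if (d < -0.5 * Lx) d += Lx;
    return d;
  }
  inline double wy(double d) const {
    if (d > 0.5 * Ly) d -= Ly; else if (d < -0.5 * Ly) d += Ly;
    return d;
  }
  inline double wz(double d) const {
    if (!periodic_z) return d;
    if (d > 0.5 * Lz) d -= Lz; else if (d < -0.5 * Lz) d += Lz;
    return d;
  }
};

// cell list over [0,Lx) x [0,Ly) x [zlo, zhi], counting-sorted so each
// cell's beads are contiguous in memory
struct CellList {
  int nx, ny, nz;
  double zlo, zspan;
  std::vector<int> start, order;
  DpdBox box;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, const DpdBox& b) {
    box = b;
    nx = std::max(1, (int)std::floor(b.Lx));
    ny = std::max(1, (int)std::floor(b.Ly));
    zlo = b.periodic_z ? 0.0 : -1.5;
    double zhi = b.periodic_z ? b.Lz : b.Lz + 1.5;
    zspan = zhi - zlo;
    nz = std::max(1, (int)std::floor(zspan));
    int n = (int)x.size();
    int ncell = nx * ny * nz;
    std::vector<int> count(ncell + 1, 0);
    std::vector<int> cid(n);
    for (int i = 0; i < n; ++i) {
      cid[i] = idx(x[i], y[i], z[i]);
      ++count[cid[i] + 1];
    }
    for (int c = 0; c < ncell; ++c) count[c + 1] += count[c];
    start = count;
    order.resize(n);
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) order[cursor[cid[i]]++] = i;
  }
  inline int idx(double x, double y, double z) const {
    int ix = (int)std::floor(x / box.Lx * nx); if (ix >= nx) ix = nx - 1; if (ix < 0) ix = 0;
    int iy = (int)std::floor(y / box.Ly * ny); if (iy >= ny) iy = ny - 1; if (iy < 0) iy = 0;
    int iz = (int)std::floor((z - zlo) / zspan * nz); if (iz >= nz) iz = nz - 1; if (iz < 0) iz = 0;
    return (iz * ny + iy) * nx + ix;
  }
};

struct DpdState {
  int n;
  std::vector<double> x, y, z, vx, vy, vz, fx, fy, fz;
  std::vector<int> type;
  std::vector<char> mobile;
  std::vector<int> b1, b2;          // bonds (0-based)
  std::vector<int> anchor_idx;
  std::vector<double> ax, ay, az;   // anchor points
  DpdBox box;
  std::vector<double> aij;          // ntype x ntype
  int ntype;
  double gamma, kT, dt, lambda, bond_k, a_cap;
  std::vector<Cap> caps;

  inline double A(int t1, int t2) const { return aij[(size_t)t1 * ntype + t2]; }
};

// conservative + dissipative + random pair forces; returns conservative
// virial sum (r . F_c) for the pressure
static double compute_forces(DpdState& S, CellList& cl, Xoshiro& rng,
                             const std::vector<double>& px,
                             const std::vector<double>& py,
                             const std::vector<double>& pz) {
  const double sigma = std::sqrt(2.0 * S.gamma * S.kT);
  const double inv_sqrt_dt = 1.0 / std::sqrt(S.dt);
  const double s3 = 1.7320508075688772;
  std::fill(S.fx.begin(), S.fx.end(), 0.0);
  std::fill(S.fy.begin(), S.fy.end(), 0.0);
  std::fill(S.fz.begin(), S.fz.end(), 0.0);
  double virial = 0.0;

  cl.build(S.x, S.y, S.z, S.box);
  int n = S.n;
  // gather into cell-sorted scratch arrays for cache locality
  static thread_local std::vector<double> sx, sy, sz, svx, svy, svz, sfx, sfy, sfz;
  static thread_local std::vector<int> sty;
  sx.resize(n); sy.resize(n); sz.resize(n);
  svx.resize(n); svy.resize(n); svz.resize(n);
  sfx.assign(n, 0.0); sfy.assign(n, 0.0); sfz.assign(n, 0.0);
  sty.resize(n);
  for (int k = 0; k < n; ++k) {
    int i = cl.order[k];
    sx[k] = S.x[i]; sy[k] = S.y[i]; sz[k] = S.z[i];
    svx[k] = px[i]; svy[k] = py[i]; svz[k] = pz[i];
    sty[k] = S.type[i];
  }
  // half-neighbour offsets (13) + self cell
  static const int off[13][3] = {
    {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
    {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};

  for (int ciz = 0; ciz < cl.nz; ++ciz) {
    for (int ciy = 0; ciy < cl.ny; ++ciy) {
      for (int cix = 0; cix < cl.nx; ++cix) {
        int c0 = (ciz * cl.ny + ciy) * cl.nx + cix;
        int i0 = cl.start[c0], i1 = cl.start[c0 + 1];
        for (int a = i0; a < i1; ++a) {
          // same cell, b after a
          for (int b = a + 1; b < i1; ++b) {
            double dx = S.box.wx(sx[a] - sx[b]);
            double dy = S.box.wy(sy[a] - sy[b]);
            double dz = S.box.wz(sz[a] - sz[b]);
            double r2 = dx * dx + dy * dy + dz * dz;
            if (r2 >= 1.0 || r2 < 1e-24) continue;
            double r = std::sqrt(r2), inv_r = 1.0 / r, w = 1.0 - r;
            double fc = S.A(sty[a], sty[b]) * w;
            double edv = (dx * (svx[a] - svx[b]) + dy * (svy[a] - svy[b])
                          + dz * (svz[a] - svz[b])) * inv_r;
            double f = (fc - S.gamma * w * w * edv
              + sigma * w * s3 * rng.runif_sym() * inv_sqrt_dt) * inv_r;
            sfx[a] += f * dx; sfy[a] += f * dy; sfz[a] += f * dz;
            sfx[b] -= f * dx; sfy[b] -= f * dy; sfz[b] -= f * dz;
            virial += fc * r;
          }
          // neighbour cells
          for (int o = 0; o < 13; ++o) {
            int jx = cix + off[o][0], jy = ciy + off[o][1], jz = ciz + off[o][2];
            if (jx < 0) jx += cl.nx; else if (jx >= cl.nx) jx -= cl.nx;
            if (jy < 0) jy += cl.ny; else if (jy >= cl.ny) jy -= cl.ny;
            if (S.box.periodic_z) {
              if (jz < 0) jz += cl.nz; else if (jz >= cl.nz) jz -= cl.nz;
            } else {
              if (jz < 0 || jz >= cl.nz) continue;
            }
            int c1 = (jz * cl.ny + jy) * cl.nx + jx;
            int j0 = cl.start[c1], j1 = cl.start[c1 + 1];
            for (int b = j0; b < j1; ++b) {
              double dx = S.box.wx(sx[a] - sx[b]);
              double dy = S.box.wy(sy[a] - sy[b]);
              double dz = S.box.wz(sz[a] - sz[b]);
              double r2 = dx * dx + dy * dy + dz * dz;
              if (r2 >= 1.0 || r2 < 1e-24) continue;
              double r = std::sqrt(r2), inv_r = 1.0 / r, w = 1.0 - r;
              double fc = S.A(sty[a], sty[b]) * w;
              double edv = (dx * (svx[a] - svx[b]) + dy * (svy[a] - svy[b])
                            + dz * (svz[a] - svz[b])) * inv_r;
              double f = (fc - S.gamma * w * w * edv
                + sigma * w * s3 * rng.runif_sym() * inv_sqrt_dt) * inv_r;
              sfx[a] += f * dx; sfy[a] += f * dy; sfz[a] += f * dz;
              sfx[b] -= f * dx; sfy[b] -= f * dy; sfz[b] -= f * dz;
              virial += fc * r;
            }
          }
        }
      }
    }
  }
  // scatter forces back to original ordering
  for (int k = 0; k < n; ++k) {
    int i = cl.order[k];
    S.fx[i] += sfx[k]; S.fy[i] += sfy[k]; S.fz[i] += sfz[k];
  }

  // harmonic bonds, natural length 0: F = -k (r_i - r_j)
  for (size_t b = 0; b < S.b1.size(); ++b) {
    int i = S.b1[b], j = S.b2[b];
    double dx = S.box.wx(S.x[i] - S.x[j]);
    double dy = S.box.wy(S.y[i] - S.y[j]);
    double dz = S.box.wz(S.z[i] - S.z[j]);
    S.fx[i] -= S.bond_k * dx; S.fy[i] -= S.bond_k * dy; S.fz[i] -= S.bond_k * dz;
    S.fx[j] += S.bond_k * dx; S.fy[j] += S.bond_k * dy; S.fz[j] += S.bond_k * dz;
  }
  // anchors (graft and pin springs to fixed sites)
  for (size_t a = 0; a < S.anchor_idx.size(); ++a) {
    int i = S.anchor_idx[a];
    double dx = S.box.wx(S.x[i] - S.ax[a]);
    double dy = S.box.wy(S.y[i] - S.ay[a]);
    double dz = S.z[i] - S.az[a];
    S.fx[i] -= S.bond_k * dx; S.fy[i] -= S.bond_k * dy; S.fz[i] -= S.bond_k * dz;
  }
  // soft planar wall forces in z: keep beads off the bounce-back planes so
  // reflections (which are not exactly energy-consistent with the
  // half-kick) stay rare
  if (!S.box.periodic_z) {
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      if (S.z[i] < 1.0) S.fz[i] += S.a_cap * (1.0 - S.z[i]);
      double dtop = S.box.Lz - S.z[i];
      if (dtop < 1.0) S.fz[i] -= S.a_cap * (1.0 - dtop);
    }
  }
  // cap obstacles: soft repulsion within 1 r_c of the ridge surface
  for (size_t c = 0; c < S.caps.size(); ++c) {
    const Cap& cp = S.caps[c];
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      double dx = S.box.wx(S.x[i] - cp.cx);
      double dz = S.z[i] - cp.cz;
      double d = std::sqrt(dx * dx + dz * dz);
      if (d >= cp.R + 1.0 || d < 1e-12) continue;
      double overlap = cp.R + 1.0 - d;   // in (0, 1] outside the solid
      double f = S.a_cap * (overlap > 1.0 ? 1.0 : overlap);
      S.fx[i] += f * dx / d;
      S.fz[i] += f * dz / d;
    }
  }
  return virial;
}

static void apply_cap_reflection(DpdState& S) {
  for (size_t c = 0; c < S.caps.size(); ++c) {
    const Cap& cp = S.caps[c];
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      double dx = S.box.wx(S.x[i] - cp.cx);
      double dz = S.z[i] - cp.cz;
      double d2 = dx * dx + dz * dz;
      if (d2 >= cp.R * cp.R || d2 < 1e-24) continue;
      double d = std::sqrt(d2);
      double ex = dx / d, ez = dz / d;
      double push = 2.0 * (cp.R - d);
      S.x[i] += push * ex;
      S.z[i] += push * ez;
      double vrad = S.vx[i] * ex + S.vz[i] * ez;
      if (vrad < 0) { S.vx[i] -= 2 * vrad * ex; S.vz[i] -= 2 * vrad * ez; }
      if (S.x[i] >= S.box.Lx) S.x[i] -= S.box.Lx;
      if (S.x[i] < 0) S.x[i] += S.box.Lx;
    }
  }
}

// [[Rcpp::export(name = ".dpd_run")]]
List dpd_run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
                 LogicalVector mobile, IntegerMatrix bonds,
                 IntegerVector anchor_idx, NumericMatrix anchor_xyz,
                 NumericVector boxv, bool periodic_z, NumericMatrix aijm,
                 double gamma, double kT, double dt, double lambda,
                 double bond_k, NumericMatrix capsm, double a_cap,
                 int n_steps, int sample_every, int seed,
                 bool do_crosslink, double p_bond, int target_nb,
                 LogicalVector active_in, IntegerVector matrix_types,
                 bool measure_pressure) {
  DpdState S;
  S.n = pos.nrow();
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  S.fx.resize(S.n); S.fy.resize(S.n); S.fz.resize(S.n);
  S.type.assign(type.begin(), type.end());
  S.mobile.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = pos(i, 0); S.y[i] = pos(i, 1); S.z[i] = pos(i, 2);
    S.vx[i] = vel(i, 0); S.vy[i] = vel(i, 1); S.vz[i] = vel(i, 2);
    S.mobile[i] = mobile[i] ? 1 : 0;
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.b1.push_back(bonds(b, 0) - 1);
    S.b2.push_back(bonds(b, 1) - 1);
  }
  for (int a = 0; a < anchor_idx.size(); ++a) {
    S.anchor_idx.push_back(anchor_idx[a] - 1);
    S.ax.push_back(anchor_xyz(a, 0));
    S.ay.push_back(anchor_xyz(a, 1));
    S.az.push_back(anchor_xyz(a, 2));
  }
  S.box.Lx = boxv[0]; S.box.Ly = boxv[1]; S.box.Lz = boxv[2];
  S.box.periodic_z = periodic_z;
  S.ntype = aijm.nrow();
  S.aij.resize((size_t)S.ntype * S.ntype);
  for (int i = 0; i < S.ntype; ++i)
    for (int j = 0; j < S.ntype; ++j)
      S.aij[(size_t)i * S.ntype + j] = aijm(i, j);
  S.gamma = gamma; S.kT = kT; S.dt = dt; S.lambda = lambda;
  S.bond_k = bond_k; S.a_cap = a_cap;
  for (int c = 0; c < capsm.nrow(); ++c) {
    Cap cp; cp.cx = capsm(c, 0); cp.cz = capsm(c, 1); cp.R = capsm(c, 2);
    S.caps.push_back(cp);
  }
  std::vector<char> active(S.n, 0);
  for (int i = 0; i < S.n; ++i) active[i] = active_in[i] ? 1 : 0;
  std::vector<char> is_matrix(S.ntype, 0);
  for (int k = 0; k < matrix_types.size(); ++k) is_matrix[matrix_types[k]] = 1;

  CellList cl;
  Xoshiro rng((uint64_t)seed);
  std::vector<double> px(S.n), py(S.n), pz(S.n);

  int n_mobile = 0;
  for (int i = 0; i < S.n; ++i) if (S.mobile[i]) ++n_mobile;

  std::vector<double> kT_trace, h_trace, p_trace, nb_trace;
  int nb_initial = 0;  // cross-links formed before this run are not counted here

  // initial forces (predicted velocities = current)
  double virial = compute_forces(S, cl, rng, S.vx, S.vy, S.vz);
  long long n_crosslinks = 0;
  for (size_t b = 0; b < S.b1.size(); ++b) (void)b;

  // thermal speeds are O(1); a bead moving faster than ~30 r_c per unit
  // time only occurs when the integration has diverged
  const double vmax2 = 1e3;

  for (int step = 0; step < n_steps; ++step) {
    // modified velocity-Verlet
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      px[i] = S.vx[i] + lambda * dt * S.fx[i];
      py[i] = S.vy[i] + lambda * dt * S.fy[i];
      pz[i] = S.vz[i] + lambda * dt * S.fz[i];
      S.x[i] += dt * S.vx[i] + 0.5 * dt * dt * S.fx[i];
      S.y[i] += dt * S.vy[i] + 0.5 * dt * dt * S.fy[i];
      S.z[i] += dt * S.vz[i] + 0.5 * dt * dt * S.fz[i];
      // wrap x, y
      if (S.x[i] >= S.box.Lx) S.x[i] -= S.box.Lx; else if (S.x[i] < 0) S.x[i] += S.box.Lx;
      if (S.y[i] >= S.box.Ly) S.y[i] -= S.box.Ly; else if (S.y[i] < 0) S.y[i] += S.box.Ly;
      if (periodic_z) {
        if (S.z[i] >= S.box.Lz) S.z[i] -= S.box.Lz; else if (S.z[i] < 0) S.z[i] += S.box.Lz;
      } else {
        // bounce-back walls at z = 0 and z = Lz
        if (S.z[i] < 0) { S.z[i] = -S.z[i]; S.vx[i] = -S.vx[i]; S.vy[i] = -S.vy[i]; S.vz[i] = -S.vz[i]; px[i] = -px[i]; py[i] = -py[i]; pz[i] = -pz[i]; }
        if (S.z[i] > S.box.Lz) { S.z[i] = 2 * S.box.Lz - S.z[i]; S.vx[i] = -S.vx[i]; S.vy[i] = -S.vy[i]; S.vz[i] = -S.vz[i]; px[i] = -px[i]; py[i] = -py[i]; pz[i] = -pz[i]; }
      }
    }
    if (!S.caps.empty()) apply_cap_reflection(S);

    std::vector<double> fx0 = S.fx, fy0 = S.fy, fz0 = S.fz;
    virial = compute_forces(S, cl, rng, px, py, pz);
    for (int i = 0; i < S.n; ++i) {
      if (!S.mobile[i]) continue;
      S.vx[i] += 0.5 * dt * (fx0[i] + S.fx[i]);
      S.vy[i] += 0.5 * dt * (fy0[i] + S.fy[i]);
      S.vz[i] += 0.5 * dt * (fz0[i] + S.fz[i]);
      double v2 = S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
      if (v2 > vmax2 || !std::isfinite(v2))
        stop("integration unstable at step %d: bead velocity overflow (reduce dt)", step + 1);
    }

    // stochastic cross-linking between active beads in contact
    if (do_crosslink && (int)n_crosslinks < target_nb) {
      std::vector<std::pair<int,int>> cand;
      // collect active-active contacts with a dedicated pass over the cell list
      cl.build(S.x, S.y, S.z, S.box);
      static const int offc[13][3] = {
        {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
        {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
      for (int ciz = 0; ciz < cl.nz; ++ciz)
        for (int ciy = 0; ciy < cl.ny; ++ciy)
          for (int cix = 0; cix < cl.nx; ++cix) {
            int c0 = (ciz * cl.ny + ciy) * cl.nx + cix;
            for (int a = cl.start[c0]; a < cl.start[c0 + 1]; ++a) {
              int i = cl.order[a];
              if (!active[i]) continue;
              for (int b = a + 1; b < cl.start[c0 + 1]; ++b) {
                int j = cl.order[b];
                if (!active[j]) continue;
                double dx = S.box.wx(S.x[i] - S.x[j]);
                double dy = S.box.wy(S.y[i] - S.y[j]);
                double dz = S.box.wz(S.z[i] - S.z[j]);
                if (dx * dx + dy * dy + dz * dz < 1.0) cand.push_back({i, j});
              }
              for (int o = 0; o < 13; ++o) {
                int jx = cix + offc[o][0], jy = ciy + offc[o][1], jz = ciz + offc[o][2];
                if (jx < 0) jx += cl.nx; else if (jx >= cl.nx) jx -= cl.nx;
                if (jy < 0) jy += cl.ny; else if (jy >= cl.ny) jy -= cl.ny;
                if (S.box.periodic_z) {
                  if (jz < 0) jz += cl.nz; else if (jz >= cl.nz) jz -= cl.nz;
                } else if (jz < 0 || jz >= cl.nz) continue;
                int c1 = (jz * cl.ny + jy) * cl.nx + jx;
                for (int b = cl.start[c1]; b < cl.start[c1 + 1]; ++b) {
                  int j = cl.order[b];
                  if (!active[j]) continue;
                  double dx = S.box.wx(S.x[i] - S.x[j]);
                  double dy = S.box.wy(S.y[i] - S.y[j]);
                  double dz = S.box.wz(S.z[i] - S.z[j]);
                  if (dx * dx + dy * dy + dz * dz < 1.0) cand.push_back({i, j});
                }
              }
            }
          }
      // randomized order; a bead consumed this step is skipped afterwards
      for (int k = (int)cand.size() - 1; k > 0; --k) {
        int m = rng.rint(k + 1);
        std::swap(cand[k], cand[m]);
      }
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k].first, j = cand[k].second;
        if (!active[i] || !active[j]) continue;
        if ((int)n_crosslinks >= target_nb) break;
        if (rng.runif() < p_bond) {
          S.b1.push_back(i); S.b2.push_back(j);
          active[i] = 0; active[j] = 0;
          ++n_crosslinks;
        }
      }
    }

    if ((step + 1) % sample_every == 0) {
      double ke = 0; int nm = 0;
      double hz = 0; int nmat = 0;
      for (int i = 0; i < S.n; ++i) {
        if (S.mobile[i]) {
          ke += S.vx[i] * S.vx[i] + S.vy[i] * S.vy[i] + S.vz[i] * S.vz[i];
          ++nm;
          if (is_matrix[S.type[i]]) { hz += S.z[i]; ++nmat; }
        }
      }
      kT_trace.push_back(nm ? ke / (3.0 * nm) : 0.0);
      h_trace.push_back(nmat ? 2.0 * hz / nmat : 0.0);
      nb_trace.push_back((double)n_crosslinks);
      if (measure_pressure) {
        double V = S.box.Lx * S.box.Ly * S.box.Lz;
        p_trace.push_back((n_mobile * (kT_trace.back()) + virial / 3.0) / V);
      }
    }
  }

  NumericMatrix outpos(S.n, 3), outvel(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    outpos(i, 0) = S.x[i]; outpos(i, 1) = S.y[i]; outpos(i, 2) = S.z[i];
    outvel(i, 0) = S.vx[i]; outvel(i, 1) = S.vy[i]; outvel(i, 2) = S.vz[i];
  }
  IntegerMatrix outbonds((int)S.b1.size(), 2);
  for (int b = 0; b < (int)S.b1.size(); ++b) {
    outbonds(b, 0) = S.b1[b] + 1; outbonds(b, 1) = S.b2[b] + 1;
  }
  LogicalVector outactive(S.n);
  for (int i = 0; i < S.n; ++i) outactive[i] = active[i] != 0;
  double momx = 0, momy = 0, momz = 0;
  for (int i = 0; i < S.n; ++i) {
    if (!S.mobile[i]) continue;
    momx += S.vx[i]; momy += S.vy[i]; momz += S.vz[i];
  }

  return List::create(
    _["pos"] = outpos, _["vel"] = outvel, _["bonds"] = outbonds,
    _["active"] = outactive,
    _["kT_trace"] = NumericVector(kT_trace.begin(), kT_trace.end()),
    _["h_trace"] = NumericVector(h_trace.begin(), h_trace.end()),
    _["p_trace"] = NumericVector(p_trace.begin(), p_trace.end()),
    _["nb_trace"] = NumericVector(nb_trace.begin(), nb_trace.end()),
    _["n_crosslinks"] = (double)n_crosslinks,
    _["momentum"] = NumericVector::create(momx, momy, momz));
}
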