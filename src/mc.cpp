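// Metropolis Monte Carlo engine for cell adsorption/detachment on a
// micropatterned surface: fixed cylindrical adhesive domains at coverage
// sigma_d, a thermoresponsive polymer phase between them (collapsed: inert;
// swollen: repulsive), hard-sphere cells settling under gravity.
//
// Reduced units: cell diameter D sets the length scale family, the effective
// noise temperature T_eff sets the energy unit. Lateral boundaries periodic,
// bottom hard wall at the maximum-deformation plane, reflecting top.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

static const double PI = 3.141592653589793;

// Area of the intersection (lens) of two discs of radii r1, r2 with centre
// distance d.
static inline double lens_area(double r1, double r2, double d) {
  if (d >= r1 + r2) return 0.0;
  double rmin = r1 < r2 ? r1 : r2;
  if (d <= std::fabs(r1 - r2)) return PI * rmin * rmin;
  double r12 = r1 * r1, r22 = r2 * r2, d2 = d * d;
  double c1 = (d2 + r12 - r22) / (2.0 * d * r1);
  double c2 = (d2 + r22 - r12) / (2.0 * d * r2);
  if (c1 > 1.0) c1 = 1.0; else if (c1 < -1.0) c1 = -1.0;
  if (c2 > 1.0) c2 = 1.0; else if (c2 < -1.0) c2 = -1.0;
  double a = r12 * std::acos(c1) + r22 * std::acos(c2)
    - 0.5 * std::sqrt(std::max(0.0, (-d + r1 + r2) * (d + r1 - r2)
                               * (d - r1 + r2) * (d + r1 + r2)));
  return a;
}

// [[Rcpp::export(name = ".circle_lens_area")]]
double circle_lens_area_cpp(double r1, double r2, double d) {
  if (r1 < 0 || r2 < 0 || d < 0) stop("radii and distance must be non-negative");
  return lens_area(r1, r2, d);
}

// --- uniform lateral grid over the fixed domain centres ------------------

struct DomainGrid {
  double L, cell;
  int ncell;
  std::vector<std::vector<int>> bins;
  const double* xs;
  const double* ys;
  int n;

  DomainGrid(const NumericMatrix& centers, double L_, double cell_target)
    : L(L_) {
    n = centers.nrow();
    ncell = std::max(1, (int)std::floor(L / cell_target));
    cell = L / ncell;
    bins.resize((size_t)ncell * ncell);
    xs = &centers(0, 0);
    ys = n > 0 ? &centers(0, 1) : xs;
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor(centers(i, 0) / cell) % ncell;
      int iy = (int)std::floor(centers(i, 1) / cell) % ncell;
      if (ix < 0) ix += ncell;
      if (iy < 0) iy += ncell;
      bins[(size_t)iy * ncell + ix].push_back(i);
    }
  }

  inline double wrap(double d) const {
    if (d > 0.5 * L) d -= L;
    else if (d < -0.5 * L) d += L;
    return d;
  }

  // sum of lens areas between a disc (radius r at x, y) and all domain
  // top discs of radius rd
  double covered_area(double x, double y, double r, double rd) const {
    if (n == 0 || r <= 0) return 0.0;
    double rq = r + rd;
    int span = (int)std::floor(rq / cell) + 1;
    int cx = (int)std::floor(x / cell), cy = (int)std::floor(y / cell);
    double total = 0.0, rq2 = rq * rq;
    for (int dy = -span; dy <= span; ++dy) {
      int iy = (cy + dy) % ncell; if (iy < 0) iy += ncell;
      for (int dx = -span; dx <= span; ++dx) {
        int ix = (cx + dx) % ncell; if (ix < 0) ix += ncell;
        const std::vector<int>& b = bins[(size_t)iy * ncell + ix];
        for (size_t k = 0; k < b.size(); ++k) {
          int i = b[k];
          double ddx = wrap(xs[i] - x), ddy = wrap(ys[i] - y);
          double d2 = ddx * ddx + ddy * ddy;
          if (d2 < rq2) total += lens_area(r, rd, std::sqrt(d2));
        }
      }
    }
    return total;
  }

  bool any_closer_than(double x, double y, double dmin) const {
    if (n == 0) return false;
    int span = (int)std::floor(dmin / cell) + 1;
    int cx = (int)std::floor(x / cell), cy = (int)std::floor(y / cell);
    double d2min = dmin * dmin;
    for (int dy = -span; dy <= span; ++dy) {
      int iy = (cy + dy) % ncell; if (iy < 0) iy += ncell;
      for (int dx = -span; dx <= span; ++dx) {
        int ix = (cx + dx) % ncell; if (ix < 0) ix += ncell;
        const std::vector<int>& b = bins[(size_t)iy * ncell + ix];
        for (size_t k = 0; k < b.size(); ++k) {
          int i = b[k];
          double ddx = wrap(xs[i] - x), ddy = wrap(ys[i] - y);
          if (ddx * ddx + ddy * ddy < d2min) return true;
        }
      }
    }
    return false;
  }
};

// --- random sequential adsorption of non-overlapping discs ----------------

// [[Rcpp::export(name = ".rsa_disks")]]
NumericMatrix rsa_disks_cpp(double L, double diam, int n_target,
                            double attempts_per_disk, int seed) {
  if (n_target == 0) return NumericMatrix(0, 2);
  Xoshiro rng((uint64_t)seed);
  std::vector<double> px, py;
  px.reserve(n_target); py.reserve(n_target);
  double cell_target = std::max(diam, L / 512.0);
  int ncell = std::max(1, (int)std::floor(L / cell_target));
  double cell = L / ncell;
  std::vector<std::vector<int>> bins((size_t)ncell * ncell);
  long long budget = (long long)(attempts_per_disk * (double)n_target);
  long long attempts = 0;
  double d2min = diam * diam;
  while ((int)px.size() < n_target && attempts < budget) {
    ++attempts;
    double x = rng.runif() * L, y = rng.runif() * L;
    int cx = (int)std::floor(x / cell), cy = (int)std::floor(y / cell);
    int span = (int)std::floor(diam / cell) + 1;
    bool ok = true;
    for (int dy = -span; dy <= span && ok; ++dy) {
      int iy = (cy + dy) % ncell; if (iy < 0) iy += ncell;
      for (int dx = -span; dx <= span && ok; ++dx) {
        int ix = (cx + dx) % ncell; if (ix < 0) ix += ncell;
        const std::vector<int>& b = bins[(size_t)iy * ncell + ix];
        for (size_t k = 0; k < b.size(); ++k) {
          int i = b[k];
          double ddx = px[i] - x; if (ddx > 0.5 * L) ddx -= L; else if (ddx < -0.5 * L) ddx += L;
          double ddy = py[i] - y; if (ddy > 0.5 * L) ddy -= L; else if (ddy < -0.5 * L) ddy += L;
          if (ddx * ddx + ddy * ddy < d2min) { ok = false; break; }
        }
      }
    }
    if (ok) {
      int id = (int)px.size();
      px.push_back(x); py.push_back(y);
      bins[(size_t)cy * ncell + cx].push_back(id);
    }
  }
  if ((int)px.size() < n_target)
    stop("RSA placement failed: %d of %d discs placed within the attempt budget",
         (int)px.size(), n_target);
  NumericMatrix out((int)px.size(), 2);
  for (int i = 0; i < (int)px.size(); ++i) { out(i, 0) = px[i]; out(i, 1) = py[i]; }
  return out;
}

// --- energy model ---------------------------------------------------------

struct McPar {
  double D;        // cell diameter
  double A[2];     // adhesion per unit area for types 1, 2 (negative)
  double Bp;       // polymer repulsion per unit area (>= 0)
  double gw;       // gravity energy per unit height
  double Teff;     // effective noise temperature
  double delta;    // max displacement half-width
  double delta_max; // max deformation depth
  double hp;       // swollen polymer height above domain tops
  double Hd;       // domain height
  double rd;       // domain top-disc radius
  double Hbox;     // box height (reflecting top)
  bool swollen;
};

// potential energy of one cell at (x, y, z); type k in {0, 1}
static double cell_energy(double x, double y, double z, int k,
                          const DomainGrid& grid, const McPar& p) {
  double E = p.gw * z;
  double R = 0.5 * p.D;
  double h = z - p.Hd;  // centre height above domain-top plane
  if (h < R) {
    double a2 = R * R - h * h;
    if (a2 > 0) {
      double a = std::sqrt(a2);
      E += p.A[k] * grid.covered_area(x, y, a, p.rd);
    }
  }
  if (p.swollen && p.Bp != 0.0) {
    double dz = z - (p.Hd + p.hp);
    if (dz < R) {
      double b = (dz <= 0.0) ? R : std::sqrt(R * R - dz * dz);
      double area = PI * b * b - grid.covered_area(x, y, b, p.rd);
      if (area < 0) area = 0;
      E += p.Bp * area;
    }
  }
  return E;
}

// [[Rcpp::export(name = ".mc_cell_energy")]]
List mc_cell_energy_cpp(NumericVector xyz, int type, NumericMatrix dom,
                        double L, List par) {
  McPar p;
  p.D = par["D"]; p.A[0] = par["A1"]; p.A[1] = par["A2"];
  p.Bp = par["Bp"]; p.gw = par["gw"]; p.Teff = par["Teff"];
  p.delta = par["delta"]; p.delta_max = par["delta_max"]; p.hp = par["hp"];
  p.Hd = par["Hd"]; p.rd = (double)par["Dd"] * 0.5; p.Hbox = par["Hbox"];
  p.swollen = par["swollen"];
  DomainGrid grid(dom, L, std::max(2.0, 2.0 * p.rd));
  double R = 0.5 * p.D;
  double x = xyz[0], y = xyz[1], z = xyz[2];
  double h = z - p.Hd;
  double contact = 0.0, repul = 0.0;
  if (h < R) {
    double a2 = R * R - h * h;
    if (a2 > 0) contact = grid.covered_area(x, y, std::sqrt(a2), p.rd);
  }
  if (p.swollen) {
    double dz = z - (p.Hd + p.hp);
    if (dz < R) {
      double b = (dz <= 0.0) ? R : std::sqrt(R * R - dz * dz);
      repul = PI * b * b - grid.covered_area(x, y, b, p.rd);
      if (repul < 0) repul = 0;
    }
  }
  double E = p.A[type - 1] * contact + p.Bp * repul + p.gw * z;
  return List::create(_["energy"] = E, _["contact_area"] = contact,
                      _["repulsion_area"] = repul);
}

static inline double wrapL(double v, double L) {
  if (v >= L) v -= L; else if (v < 0) v += L;
  return v;
}

// [[Rcpp::export(name = ".mc_run")]]
List mc_run_cpp(NumericMatrix dom, double L, NumericMatrix cells0,
                IntegerVector ctype, List par, double n_moves,
                int sample_every, int seed, bool record_z,
                double rcut) {
  McPar p;
  p.D = par["D"]; p.A[0] = par["A1"]; p.A[1] = par["A2"];
  p.Bp = par["Bp"]; p.gw = par["gw"]; p.Teff = par["Teff"];
  p.delta = par["delta"]; p.delta_max = par["delta_max"]; p.hp = par["hp"];
  p.Hd = par["Hd"]; p.rd = (double)par["Dd"] * 0.5; p.Hbox = par["Hbox"];
  p.swollen = par["swollen"];

  int N = cells0.nrow();
  std::vector<double> x(N), y(N), z(N);
  std::vector<int> typ(N);
  for (int i = 0; i < N; ++i) {
    x[i] = cells0(i, 0); y[i] = cells0(i, 1); z[i] = cells0(i, 2);
    typ[i] = ctype[i] - 1;
  }
  double zwall = p.Hd + 0.5 * p.D - p.delta_max;
  double D2 = p.D * p.D;

  DomainGrid grid(dom, L, std::max(2.0, 2.0 * p.rd));
  Xoshiro rng((uint64_t)seed);

  std::vector<double> E(N);
  for (int i = 0; i < N; ++i) E[i] = cell_energy(x[i], y[i], z[i], typ[i], grid, p);

  long long nm = (long long)n_moves;
  long long accepted = 0;
  long long half = nm / 2;
  int nsamp_max = (int)(nm / sample_every) + 2;
  std::vector<double> etrace; etrace.reserve(nsamp_max);
  std::vector<double> att1; att1.reserve(nsamp_max);
  std::vector<double> att2; att2.reserve(nsamp_max);
  std::vector<double> zsamp;
  if (record_z) zsamp.reserve((size_t)nsamp_max * N);

  double sum_att1 = 0, sum_att2 = 0; long long n_att_samp = 0;
  int n1 = 0, n2 = 0;
  for (int i = 0; i < N; ++i) (typ[i] == 0 ? n1 : n2)++;

  for (long long step = 0; step < nm; ++step) {
    int i = rng.rint(N);
    double nx = wrapL(x[i] + p.delta * rng.runif_sym(), L);
    double ny = wrapL(y[i] + p.delta * rng.runif_sym(), L);
    double nz = z[i] + p.delta * rng.runif_sym();
    bool ok = (nz >= zwall && nz <= p.Hbox);
    if (ok) {
      for (int j = 0; j < N; ++j) {
        if (j == i) continue;
        double ddx = nx - x[j]; if (ddx > 0.5 * L) ddx -= L; else if (ddx < -0.5 * L) ddx += L;
        double ddy = ny - y[j]; if (ddy > 0.5 * L) ddy -= L; else if (ddy < -0.5 * L) ddy += L;
        double ddz = nz - z[j];
        if (ddx * ddx + ddy * ddy + ddz * ddz < D2) { ok = false; break; }
      }
    }
    if (ok) {
      double Enew = cell_energy(nx, ny, nz, typ[i], grid, p);
      double dE = Enew - E[i];
      if (dE <= 0.0 || rng.runif() < std::exp(-dE / p.Teff)) {
        x[i] = nx; y[i] = ny; z[i] = nz; E[i] = Enew;
        ++accepted;
      }
    }
    if ((step + 1) % sample_every == 0) {
      double etot = 0; int a1 = 0, a2 = 0;
      for (int j = 0; j < N; ++j) {
        etot += E[j];
        if (z[j] - p.Hd <= rcut) (typ[j] == 0 ? a1 : a2)++;
      }
      etrace.push_back(etot);
      att1.push_back(100.0 * a1 / std::max(1, n1));
      att2.push_back(100.0 * a2 / std::max(1, n2));
      if (step >= half) {
        sum_att1 += a1; sum_att2 += a2; ++n_att_samp;
        if (record_z) for (int j = 0; j < N; ++j) zsamp.push_back(z[j]);
      }
    }
  }

  NumericMatrix pos(N, 3);
  for (int i = 0; i < N; ++i) { pos(i, 0) = x[i]; pos(i, 1) = y[i]; pos(i, 2) = z[i]; }

  List out = List::create(
    _["pos"] = pos,
    _["acc_rate"] = (double)accepted / (double)nm,
    _["energy_trace"] = NumericVector(etrace.begin(), etrace.end()),
    _["attached1_trace"] = NumericVector(att1.begin(), att1.end()),
    _["attached2_trace"] = NumericVector(att2.begin(), att2.end()),
    _["frac1"] = n_att_samp ? 100.0 * sum_att1 / n_att_samp / std::max(1, n1) : NA_REAL,
    _["frac2"] = n_att_samp ? 100.0 * sum_att2 / n_att_samp / std::max(1, n2) : NA_REAL);
  if (record_z) {
    NumericVector zs(zsamp.begin(), zsamp.end());
    out["z_samples"] = zs;
    out["z_types"] = IntegerVector(typ.begin(), typ.end());
  }
  return out;
}

// Empirical Metropolis acceptance frequency at fixed energy difference,
// using the engine's own RNG and acceptance rule.
// [[Rcpp::export(name = ".mc_accept_freq")]]
double mc_accept_freq_cpp(double dE, double Teff, int n, int seed) {
  Xoshiro rng((uint64_t)seed);
  long long acc = 0;
  for (int i = 0; i < n; ++i) {
    if (dE <= 0.0 || rng.runif() < std::exp(-dE / Teff)) ++acc;
  }
  return (double)acc / n;
}
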