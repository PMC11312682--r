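// Compiled kernels: batch dimer configuration energies, the periodic MD
// integrator with Andersen thermostat, box energy/gradient, and neighbor
// counting (brute force and cell index). Units: Angstrom, fs, amu,
// kcal/mol, elementary charges.
#include <Rcpp.h>
#include <vector>
#include <set>
#include <cmath>
using namespace Rcpp;

static const double KB = 1.987204259e-3;     // kcal/(mol K)
static const double ECONV = 4.184e-4;        // (kcal/mol/A)/amu -> A/fs^2

struct Mat3 {
  double m[9];
  inline void apply(const double* v, double* out) const {
    out[0] = m[0] * v[0] + m[1] * v[1] + m[2] * v[2];
    out[1] = m[3] * v[0] + m[4] * v[1] + m[5] * v[2];
    out[2] = m[6] * v[0] + m[7] * v[1] + m[8] * v[2];
  }
};

// minimal rotation mapping unit vector p onto unit vector t (Rodrigues);
// antiparallel case: 180 degrees about a fixed fallback axis perpendicular
// to t. Mirrored by the R-level orient_to_axis().
static Mat3 rotation_to(const double* p, const double* t) {
  Mat3 R;
  double c = p[0] * t[0] + p[1] * t[1] + p[2] * t[2];
  if (c < -1.0 + 1e-12) {
    double a[3] = {1.0, 0.0, 0.0};
    if (std::fabs(t[0]) > 0.9) { a[0] = 0.0; a[1] = 1.0; }
    double d = a[0] * t[0] + a[1] * t[1] + a[2] * t[2];
    for (int i = 0; i < 3; ++i) a[i] -= d * t[i];
    double n = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
    for (int i = 0; i < 3; ++i) a[i] /= n;
    // R = I + 2 K^2 = 2 a a^T - I
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        R.m[3 * i + j] = 2.0 * a[i] * a[j] - (i == j ? 1.0 : 0.0);
    return R;
  }
  double v0 = p[1] * t[2] - p[2] * t[1];
  double v1 = p[2] * t[0] - p[0] * t[2];
  double v2 = p[0] * t[1] - p[1] * t[0];
  double f = 1.0 / (1.0 + c);
  R.m[0] = 1.0 + f * (-v2 * v2 - v1 * v1);
  R.m[1] = -v2 + f * (v0 * v1);
  R.m[2] = v1 + f * (v0 * v2);
  R.m[3] = v2 + f * (v0 * v1);
  R.m[4] = 1.0 + f * (-v2 * v2 - v0 * v0);
  R.m[5] = -v0 + f * (v1 * v2);
  R.m[6] = -v1 + f * (v0 * v2);
  R.m[7] = v0 + f * (v1 * v2);
  R.m[8] = 1.0 + f * (-v1 * v1 - v0 * v0);
  return R;
}

static inline double pow7(double x) {
  double x2 = x * x, x4 = x2 * x2;
  return x4 * x2 * x;
}

// pair energy sum over ni x nj intermolecular pairs
static double pair_sum(const std::vector<double>& xi,
                       const std::vector<double>& xj,
                       int ni, int nj,
                       const double* rmat, const double* epsmat,
                       const double* qqmat, int vdw_form,
                       bool elec_buffered) {
  double e = 0.0;
  for (int i = 0; i < ni; ++i) {
    const double* a = &xi[3 * i];
    for (int j = 0; j < nj; ++j) {
      const double* b = &xj[3 * j];
      double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double rm = rmat[i + (size_t)ni * j];
      double eps = epsmat[i + (size_t)ni * j];
      if (vdw_form == 0) {
        double sr2 = rm * rm / (r * r);
        double sr6 = sr2 * sr2 * sr2;
        e += 4.0 * eps * (sr6 * sr6 - sr6);
      } else {
        double t1 = 1.07 * rm / (r + 0.07 * rm);
        e += eps * pow7(t1) *
          (1.12 * pow7(rm) / (pow7(r) + 0.12 * pow7(rm)) - 2.0);
      }
      e += qqmat[i + (size_t)ni * j] / (elec_buffered ? r + 0.05 : r);
    }
  }
  return e;
}

// [[Rcpp::export]]
NumericVector cpp_config_energy(NumericMatrix xi, NumericMatrix xj,
                                NumericMatrix rmat, NumericMatrix epsmat,
                                NumericMatrix qqmat, int vdw_form,
                                bool elec_buffered) {
  int ni = xi.nrow(), nj = xj.nrow();
  std::vector<double> a(3 * ni), b(3 * nj);
  for (int i = 0; i < ni; ++i)
    for (int k = 0; k < 3; ++k) a[3 * i + k] = xi(i, k);
  for (int j = 0; j < nj; ++j)
    for (int k = 0; k < 3; ++k) b[3 * j + k] = xj(j, k);
  double e = pair_sum(a, b, ni, nj, &rmat(0, 0), &epsmat(0, 0),
                      &qqmat(0, 0), vdw_form, elec_buffered);
  return NumericVector::create(e);
}

// Energies of all n_sphere^2 x n_rot rigid dimer configurations at center
// separation r_fix. xi, xj are centered monomer coordinates; lattice holds
// the unit sphere points. Index layout (R side, 1-based):
// idx = ((a-1)*Ns + (b-1))*n_rot + k.
// [[Rcpp::export]]
NumericVector cpp_enumerate_energies(NumericMatrix xi, NumericMatrix xj,
                                     NumericMatrix lattice, int n_rot,
                                     double r_fix, NumericMatrix rmat,
                                     NumericMatrix epsmat,
                                     NumericMatrix qqmat, int vdw_form,
                                     bool elec_buffered) {
  int ns = lattice.nrow();
  int ni = xi.nrow(), nj = xj.nrow();
  const double ex[3] = {1.0, 0.0, 0.0};
  const double mex[3] = {-1.0, 0.0, 0.0};

  // pre-rotate molecule i for every lattice point (point -> +x)
  std::vector<std::vector<double>> xi_rot(ns, std::vector<double>(3 * ni));
  std::vector<std::vector<double>> xj_rot(ns, std::vector<double>(3 * nj));
  for (int a = 0; a < ns; ++a) {
    double p[3] = {lattice(a, 0), lattice(a, 1), lattice(a, 2)};
    Mat3 Ri = rotation_to(p, ex);
    Mat3 Rj = rotation_to(p, mex);
    for (int i = 0; i < ni; ++i) {
      double v[3] = {xi(i, 0), xi(i, 1), xi(i, 2)};
      Ri.apply(v, &xi_rot[a][3 * i]);
    }
    for (int j = 0; j < nj; ++j) {
      double v[3] = {xj(j, 0), xj(j, 1), xj(j, 2)};
      Rj.apply(v, &xj_rot[a][3 * j]);
    }
  }

  NumericVector out((R_xlen_t)ns * ns * n_rot);
  std::vector<double> xj_cfg(3 * nj);
  for (int b = 0; b < ns; ++b) {
    for (int k = 0; k < n_rot; ++k) {
      double ang = 2.0 * M_PI * k / n_rot;
      double ca = std::cos(ang), sa = std::sin(ang);
      // spin about the center-center (x) axis, then translate to r_fix
      for (int j = 0; j < nj; ++j) {
        const double* v = &xj_rot[b][3 * j];
        xj_cfg[3 * j] = v[0] + r_fix;
        xj_cfg[3 * j + 1] = ca * v[1] - sa * v[2];
        xj_cfg[3 * j + 2] = sa * v[1] + ca * v[2];
      }
      for (int a = 0; a < ns; ++a) {
        double e = pair_sum(xi_rot[a], xj_cfg, ni, nj, &rmat(0, 0),
                            &epsmat(0, 0), &qqmat(0, 0), vdw_form,
                            elec_buffered);
        out[((R_xlen_t)a * ns + b) * n_rot + k] = e;
      }
    }
  }
  return out;
}

static inline double min_image(double d, double edge, bool pbc) {
  if (!pbc) return d;
  d -= edge * std::round(d / edge);
  return d;
}

// Potential energy and gradient of a (periodic) box: LJ (Lorentz-Berthelot)
// + Coulomb between atoms of different molecules within the cutoff, plus
// harmonic distance restraints (i, j, r0, k) that stand in for the
// intramolecular geometry.
// [[Rcpp::export]]
List cpp_box_energy_gradient(NumericMatrix pos, IntegerVector molidx,
                             NumericVector sigma, NumericVector eps,
                             NumericVector q, NumericMatrix restraints,
                             double edge, double cutoff,
                             double coulomb_c, double dielectric,
                             bool use_pbc) {
  int n = pos.nrow();
  NumericMatrix grad(n, 3);
  double energy = 0.0;
  double cut2 = cutoff > 0 ? cutoff * cutoff : R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (molidx[i] == molidx[j]) continue;
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = min_image(pos(i, k) - pos(j, k), edge, use_pbc);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 > cut2) continue;
      double r = std::sqrt(r2);
      double s = 0.5 * (sigma[i] + sigma[j]);
      double e = std::sqrt(eps[i] * eps[j]);
      double dEdr = 0.0;
      if (e > 0.0 && s > 0.0) {
        double sr2 = s * s / r2;
        double sr6 = sr2 * sr2 * sr2;
        energy += 4.0 * e * (sr6 * sr6 - sr6);
        dEdr += 4.0 * e * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
      }
      double qq = coulomb_c * q[i] * q[j] / dielectric;
      if (qq != 0.0) {
        energy += qq / r;
        dEdr += -qq / r2;
      }
      for (int k = 0; k < 3; ++k) {
        double g = dEdr * d[k] / r;
        grad(i, k) += g;
        grad(j, k) -= g;
      }
    }
  }
  int m = restraints.nrow();
  for (int b = 0; b < m; ++b) {
    int i = (int)restraints(b, 0) - 1;
    int j = (int)restraints(b, 1) - 1;
    double r0 = restraints(b, 2), kk = restraints(b, 3);
    double d[3];
    for (int k = 0; k < 3; ++k)
      d[k] = min_image(pos(i, k) - pos(j, k), edge, use_pbc);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    energy += kk * (r - r0) * (r - r0);
    double dEdr = 2.0 * kk * (r - r0);
    for (int k = 0; k < 3; ++k) {
      double g = dEdr * d[k] / r;
      grad(i, k) += g;
      grad(j, k) -= g;
    }
  }
  return List::create(_["energy"] = energy, _["gradient"] = grad);
}

static void forces_inplace(const NumericMatrix& pos, const IntegerVector& molidx,
                           const NumericVector& sigma, const NumericVector& eps,
                           const NumericVector& q, const NumericMatrix& restraints,
                           double edge, double cutoff, double coulomb_c,
                           double dielectric, bool use_pbc,
                           std::vector<double>& force, double& potential) {
  int n = pos.nrow();
  std::fill(force.begin(), force.end(), 0.0);
  potential = 0.0;
  double cut2 = cutoff > 0 ? cutoff * cutoff : R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (molidx[i] == molidx[j]) continue;
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = min_image(pos(i, k) - pos(j, k), edge, use_pbc);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 > cut2) continue;
      double r = std::sqrt(r2);
      double s = 0.5 * (sigma[i] + sigma[j]);
      double e = std::sqrt(eps[i] * eps[j]);
      double dEdr = 0.0;
      if (e > 0.0 && s > 0.0) {
        double sr2 = s * s / r2;
        double sr6 = sr2 * sr2 * sr2;
        potential += 4.0 * e * (sr6 * sr6 - sr6);
        dEdr += 4.0 * e * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
      }
      double qq = coulomb_c * q[i] * q[j] / dielectric;
      if (qq != 0.0) {
        potential += qq / r;
        dEdr += -qq / r2;
      }
      for (int k = 0; k < 3; ++k) {
        double f = -dEdr * d[k] / r;
        force[3 * i + k] += f;
        force[3 * j + k] -= f;
      }
    }
  }
  int m = restraints.nrow();
  for (int b = 0; b < m; ++b) {
    int i = (int)restraints(b, 0) - 1;
    int j = (int)restraints(b, 1) - 1;
    double r0 = restraints(b, 2), kk = restraints(b, 3);
    double d[3];
    for (int k = 0; k < 3; ++k)
      d[k] = min_image(pos(i, k) - pos(j, k), edge, use_pbc);
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    potential += kk * (r - r0) * (r - r0);
    double dEdr = 2.0 * kk * (r - r0);
    for (int k = 0; k < 3; ++k) {
      double f = -dEdr * d[k] / r;
      force[3 * i + k] += f;
      force[3 * j + k] -= f;
    }
  }
}

// Velocity-Verlet MD with minimum-image periodic boundaries and an Andersen
// thermostat (collision probability nu*dt per atom per step; velocities
// redrawn from the Maxwell-Boltzmann distribution using R's RNG so runs are
// reproducible under set.seed). Frames are recorded every record_interval
// steps after equil_steps.
// [[Rcpp::export]]
List cpp_run_md(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                IntegerVector molidx, NumericVector sigma, NumericVector eps,
                NumericVector q, NumericMatrix restraints, double edge,
                double cutoff, double dt, int equil_steps, int prod_steps,
                int record_interval, double nu, double temperature,
                double coulomb_c, double dielectric, bool use_pbc,
                bool record_positions) {
  int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  std::vector<double> force(3 * n), newforce(3 * n);
  double potential = 0.0;
  forces_inplace(pos, molidx, sigma, eps, q, restraints, edge, cutoff,
                 coulomb_c, dielectric, use_pbc, force, potential);
  List frames;
  std::vector<int> rec_steps;
  std::vector<double> pot_series, kin_series;
  int total = equil_steps + prod_steps;
  RNGScope scope;
  for (int step = 1; step <= total; ++step) {
    // velocity Verlet
    for (int i = 0; i < n; ++i) {
      double am = ECONV / mass[i];
      for (int k = 0; k < 3; ++k) {
        vel(i, k) += 0.5 * dt * am * force[3 * i + k];
        pos(i, k) += dt * vel(i, k);
      }
    }
    if (use_pbc) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) {
          double x = pos(i, k);
          x -= edge * std::floor(x / edge);
          pos(i, k) = x;
        }
    }
    forces_inplace(pos, molidx, sigma, eps, q, restraints, edge, cutoff,
                   coulomb_c, dielectric, use_pbc, newforce, potential);
    for (int i = 0; i < n; ++i) {
      double am = ECONV / mass[i];
      for (int k = 0; k < 3; ++k)
        vel(i, k) += 0.5 * dt * am * newforce[3 * i + k];
    }
    force.swap(newforce);
    if (!R_FINITE(potential) || std::fabs(potential) > 1e10)
      stop("energy diverged during MD; pre-minimize the box");
    // Andersen thermostat
    if (nu > 0.0) {
      double p_coll = nu * dt;
      for (int i = 0; i < n; ++i) {
        if (unif_rand() < p_coll) {
          double sd = std::sqrt(KB * temperature * ECONV / mass[i]);
          for (int k = 0; k < 3; ++k) vel(i, k) = sd * norm_rand();
        }
      }
    }
    if (step > equil_steps && record_interval > 0 &&
        (step - equil_steps) % record_interval == 0) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        double v2 = vel(i, 0) * vel(i, 0) + vel(i, 1) * vel(i, 1) +
          vel(i, 2) * vel(i, 2);
        ke += 0.5 * mass[i] * v2 / ECONV;
      }
      rec_steps.push_back(step);
      pot_series.push_back(potential);
      kin_series.push_back(ke);
      if (record_positions) frames.push_back(clone(pos));
    }
  }
  return List::create(
    _["frames"] = frames, _["steps"] = wrap(rec_steps),
    _["potential"] = wrap(pot_series), _["kinetic"] = wrap(kin_series),
    _["final_positions"] = pos, _["final_velocities"] = vel);
}

// shared neighbor test: molecule j is a neighbor of the solute when any of
// its atoms lies within (r_i + r_j + catch) of any solute atom
// ("less than or equal to").
// [[Rcpp::export]]
int cpp_count_neighbors_brute(NumericMatrix pos, IntegerVector molidx,
                              int solute_mol, NumericVector radii,
                              double catch_radius, double edge,
                              bool use_pbc) {
  int n = pos.nrow();
  std::vector<int> sol_atoms;
  for (int i = 0; i < n; ++i)
    if (molidx[i] == solute_mol) sol_atoms.push_back(i);
  std::set<int> counted;
  for (int j = 0; j < n; ++j) {
    if (molidx[j] == solute_mol) continue;
    if (counted.count(molidx[j])) continue;
    for (size_t a = 0; a < sol_atoms.size(); ++a) {
      int i = sol_atoms[a];
      double thr = radii[i] + radii[j] + catch_radius;
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = min_image(pos(i, k) - pos(j, k), edge, use_pbc);
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 <= thr * thr) { counted.insert(molidx[j]); break; }
    }
  }
  return (int)counted.size();
}

// [[Rcpp::export]]
int cpp_count_neighbors_cell(NumericMatrix pos, IntegerVector molidx,
                             int solute_mol, NumericVector radii,
                             double catch_radius, double edge,
                             int ncell) {
  int n = pos.nrow();
  double cell = edge / ncell;
  // bin all non-solute atoms
  std::vector<std::vector<int>> bins(ncell * ncell * ncell);
  std::vector<int> sol_atoms;
  for (int i = 0; i < n; ++i) {
    if (molidx[i] == solute_mol) { sol_atoms.push_back(i); continue; }
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double x = pos(i, k);
      x -= edge * std::floor(x / edge);
      c[k] = (int)(x / cell);
      if (c[k] >= ncell) c[k] = ncell - 1;
    }
    bins[(c[0] * ncell + c[1]) * ncell + c[2]].push_back(i);
  }
  std::set<int> counted;
  for (size_t a = 0; a < sol_atoms.size(); ++a) {
    int i = sol_atoms[a];
    double xi[3];
    int ci[3];
    for (int k = 0; k < 3; ++k) {
      double x = pos(i, k);
      x -= edge * std::floor(x / edge);
      xi[k] = x;
      ci[k] = (int)(x / cell);
      if (ci[k] >= ncell) ci[k] = ncell - 1;
    }
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          int cx = (ci[0] + dx + ncell) % ncell;
          int cy = (ci[1] + dy + ncell) % ncell;
          int cz = (ci[2] + dz + ncell) % ncell;
          const std::vector<int>& bin = bins[(cx * ncell + cy) * ncell + cz];
          for (size_t t = 0; t < bin.size(); ++t) {
            int j = bin[t];
            if (counted.count(molidx[j])) continue;
            double thr = radii[i] + radii[j] + catch_radius;
            double d0 = min_image(xi[0] - pos(j, 0), edge, true);
            double d1 = min_image(xi[1] - pos(j, 1), edge, true);
            double d2 = min_image(xi[2] - pos(j, 2), edge, true);
            if (d0 * d0 + d1 * d1 + d2 * d2 <= thr * thr)
              counted.insert(molidx[j]);
          }
        }
  }
  return (int)counted.size();
}
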