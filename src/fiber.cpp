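#include <Rcpp.h>
using namespace Rcpp;

// Energies and forces for a covalently closed ring of beads:
//   bond      1/2 kb (r - d0)^2 over ring bonds (i, i+1 mod N)
//   nonbonded repulsion over non-bonded pairs within the cutoff,
//             energy-shifted to zero at the cutoff:
//               type 1: exp(beta - alpha r)
//               type 2: A/(r - B), linearly continued (constant force)
//                       for r <= B + 0.5 A; continuation events counted
//   attraction -eps exp(-(r - r0)^2 / (2 w^2)) over the same pairs
// Units: kcal/mol, Angstrom, ps, Da.

struct FF {
  double kb, d0;          // bond
  int nb_type;            // 0 none, 1 exponential, 2 shifted Coulomb
  double alpha, beta, A, B;
  double eps, r0, w;      // Gaussian attraction (eps = 0 disables)
  double cutoff, vshift;  // repulsion value at cutoff
};

static const double CLAMP_MARGIN = 0.5;  // A above the 1/(d-B) singularity

static inline double rep_energy(const FF& ff, double r, int& n_clamped) {
  if (ff.nb_type == 1) {
    return exp(ff.beta - ff.alpha * r) - ff.vshift;
  } else if (ff.nb_type == 2) {
    double rc = ff.B + CLAMP_MARGIN;
    if (r > rc) return ff.A / (r - ff.B) - ff.vshift;
    n_clamped++;
    double slope = -ff.A / (CLAMP_MARGIN * CLAMP_MARGIN);
    return ff.A / CLAMP_MARGIN + slope * (r - rc) - ff.vshift;
  }
  return 0.0;
}

// dV/dr of the repulsion
static inline double rep_dvdr(const FF& ff, double r) {
  if (ff.nb_type == 1) {
    return -ff.alpha * exp(ff.beta - ff.alpha * r);
  } else if (ff.nb_type == 2) {
    double rc = ff.B + CLAMP_MARGIN;
    if (r > rc) return -ff.A / ((r - ff.B) * (r - ff.B));
    return -ff.A / (CLAMP_MARGIN * CLAMP_MARGIN);
  }
  return 0.0;
}

static FF unpack_ff(const List& ffl) {
  FF ff;
  ff.kb = as<double>(ffl["bond_k"]);
  ff.d0 = as<double>(ffl["bond_d0"]);
  ff.nb_type = as<int>(ffl["nb_type"]);
  ff.alpha = as<double>(ffl["alpha"]);
  ff.beta = as<double>(ffl["beta"]);
  ff.A = as<double>(ffl["A"]);
  ff.B = as<double>(ffl["B"]);
  ff.eps = as<double>(ffl["eps"]);
  ff.r0 = as<double>(ffl["r0"]);
  ff.w = as<double>(ffl["w"]);
  ff.cutoff = as<double>(ffl["cutoff"]);
  int dummy = 0;
  ff.vshift = 0.0;
  ff.vshift = rep_energy(ff, ff.cutoff, dummy);
  return ff;
}

// Accumulate energies and (optionally) forces. positions: N x 3.
static void eval_system(const NumericMatrix& x, const FF& ff,
                        bool want_forces, NumericMatrix& f,
                        double& e_bond, double& e_nb, double& e_att,
                        int& n_clamped) {
  int N = x.nrow();
  e_bond = e_nb = e_att = 0.0;
  n_clamped = 0;
  if (want_forces) std::fill(f.begin(), f.end(), 0.0);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      bool bonded = (j == i + 1) || (i == 0 && j == N - 1);
      double dx = x(i, 0) - x(j, 0);
      double dy = x(i, 1) - x(j, 1);
      double dz = x(i, 2) - x(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      double dvdr = 0.0;
      if (bonded) {
        e_bond += 0.5 * ff.kb * (r - ff.d0) * (r - ff.d0);
        dvdr += ff.kb * (r - ff.d0);
      } else if (r < ff.cutoff) {
        e_nb += rep_energy(ff, r, n_clamped);
        dvdr += rep_dvdr(ff, r);
        if (ff.eps > 0.0) {
          double z = (r - ff.r0) / ff.w;
          double g = std::exp(-0.5 * z * z);
          e_att += -ff.eps * g;
          dvdr += ff.eps * (r - ff.r0) / (ff.w * ff.w) * g;
        }
      }
      if (want_forces && dvdr != 0.0 && r > 0.0) {
        double fac = -dvdr / r;   // force on i along (xi - xj)
        f(i, 0) += fac * dx; f(i, 1) += fac * dy; f(i, 2) += fac * dz;
        f(j, 0) -= fac * dx; f(j, 1) -= fac * dy; f(j, 2) -= fac * dz;
      }
    }
  }
}

// [[Rcpp::export]]
List fiber_energy_forces(NumericMatrix positions, List ff_list,
                         bool forces = true) {
  FF ff = unpack_ff(ff_list);
  int N = positions.nrow();
  NumericMatrix f(N, 3);
  double eb, en, ea;
  int ncl;
  eval_system(positions, ff, forces, f, eb, en, ea, ncl);
  return List::create(_["e_bond"] = eb, _["e_nonbonded"] = en,
                      _["e_attraction"] = ea, _["forces"] = f,
                      _["n_clamped"] = ncl);
}

// BAOAB Langevin integrator. Masses per bead (Da), gamma in 1/ps,
// kT in kcal/mol. acc_conv converts (kcal/mol/A)/Da to A/ps^2 (418.4).
// Crash detection: non-finite coordinate/force or any bond longer than
// crash_bond_max stops the run; frames up to the failure are returned.
// [[Rcpp::export]]
List run_baoab(NumericMatrix positions, NumericMatrix velocities,
               NumericVector masses, List ff_list, double dt, int n_steps,
               int save_stride, double gamma, double kT,
               double crash_bond_max, double acc_conv) {
  FF ff = unpack_ff(ff_list);
  int N = positions.nrow();
  NumericMatrix x(clone(positions));
  NumericMatrix v(clone(velocities));
  NumericMatrix f(N, 3);
  double eb, en, ea;
  int ncl, total_clamped = 0;

  // + initial frame + possibly one off-stride crash frame
  int n_save = n_steps / save_stride + 2;
  NumericVector frames(Dimension(N, 3, n_save));
  NumericVector times(n_save);
  NumericMatrix elog(n_save, 4);  // e_bond, e_nb, e_attr, ke
  int crash_step = -1;
  std::string crash_reason = "";

  double c1 = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  std::vector<double> csd(N);
  for (int i = 0; i < N; ++i) {
    csd[i] = (gamma > 0.0 && kT > 0.0)
      ? std::sqrt(kT * acc_conv / masses[i] * (1.0 - c1 * c1)) : 0.0;
  }

  eval_system(x, ff, true, f, eb, en, ea, ncl);
  total_clamped += ncl;

  int k = 0;
  auto record = [&](double t) {
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c)
        frames[i + N * c + 3 * N * k] = x(i, c);
    times[k] = t;
    double ke = 0.0;
    for (int i = 0; i < N; ++i)
      ke += 0.5 * masses[i] *
        (v(i,0)*v(i,0) + v(i,1)*v(i,1) + v(i,2)*v(i,2));
    elog(k, 0) = eb; elog(k, 1) = en; elog(k, 2) = ea;
    elog(k, 3) = ke / acc_conv;  // kcal/mol
    k++;
  };
  record(0.0);

  for (int s = 1; s <= n_steps; ++s) {
    // B: half kick
    for (int i = 0; i < N; ++i) {
      double a = 0.5 * dt * acc_conv / masses[i];
      v(i,0) += a * f(i,0); v(i,1) += a * f(i,1); v(i,2) += a * f(i,2);
    }
    // A: half drift
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) x(i,c) += 0.5 * dt * v(i,c);
    // O: Ornstein-Uhlenbeck
    if (gamma > 0.0) {
      for (int i = 0; i < N; ++i)
        for (int c = 0; c < 3; ++c)
          v(i,c) = c1 * v(i,c) + csd[i] * R::norm_rand();
    }
    // A: half drift
    for (int i = 0; i < N; ++i)
      for (int c = 0; c < 3; ++c) x(i,c) += 0.5 * dt * v(i,c);
    // forces at new positions, B: half kick
    eval_system(x, ff, true, f, eb, en, ea, ncl);
    total_clamped += ncl;
    for (int i = 0; i < N; ++i) {
      double a = 0.5 * dt * acc_conv / masses[i];
      v(i,0) += a * f(i,0); v(i,1) += a * f(i,1); v(i,2) += a * f(i,2);
    }
    // crash diagnostics
    bool bad = false;
    for (int i = 0; i < N && !bad; ++i)
      for (int c = 0; c < 3; ++c)
        if (!std::isfinite(x(i,c)) || !std::isfinite(v(i,c)) ||
            !std::isfinite(f(i,c))) { bad = true; break; }
    if (bad) { crash_step = s; crash_reason = "non-finite state"; }
    if (!bad) {
      for (int i = 0; i < N; ++i) {
        int j = (i + 1) % N;
        double dx = x(i,0)-x(j,0), dy = x(i,1)-x(j,1), dz = x(i,2)-x(j,2);
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (!(r <= crash_bond_max)) {
          crash_step = s;
          crash_reason = "bond length exceeded crash threshold";
          break;
        }
      }
    }
    if (crash_step >= 0) { record(s * dt); break; }
    if (s % save_stride == 0) record(s * dt);
  }

  // trim to recorded frames
  NumericVector frames_out(Dimension(N, 3, k));
  std::copy(frames.begin(), frames.begin() + (R_xlen_t)N * 3 * k,
            frames_out.begin());
  return List::create(
    _["frames"] = frames_out,
    _["times"] = NumericVector(times.begin(), times.begin() + k),
    _["energies"] = elog(Range(0, k - 1), Range(0, 3)),
    _["velocities"] = v,
    _["crash_step"] = crash_step,
    _["crash_reason"] = crash_reason,
    _["n_clamped"] = total_clamped);
}
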