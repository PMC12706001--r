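// Underdamped Langevin dynamics (BAOAB splitting) for coarse-grained
// bead systems: harmonic bonds/angles at built rest geometry, 12-10 Go
// native contacts, Debye-Hueckel electrostatics, shifted r^-12 excluded
// volume, harmonic positional restraints on anchored beads, soft tether
// springs.  Verlet neighbour list over a precomputed candidate pair set.
// Units: nm, kcal/mol; kB = 0.0019872041 kcal/mol/K.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

static const double KB = 0.0019872041;

struct Vec { double x, y, z; };

// [[Rcpp::export(name = ".cg_run")]]
List cg_run(NumericMatrix pos0,
            NumericVector charge,
            NumericVector sigma_bead,
            LogicalVector anchored,
            IntegerMatrix bonds,        // 0-based i, j
            NumericVector bond_r0,
            IntegerMatrix angles,       // 0-based i, j, k
            NumericVector angle_th0,
            IntegerMatrix contacts,     // 0-based i, j
            NumericVector contact_r0,
            NumericVector contact_eps,
            IntegerMatrix tethers,      // 0-based i, j
            IntegerVector cand_i,       // candidate nonbonded pairs
            IntegerVector cand_j,
            LogicalVector cand_ev,
            IntegerVector track_low,    // 0-based bead rows
            IntegerVector track_high,
            List par,                   // engine parameters
            bool output_full) {
  const int n = pos0.nrow();
  const double dt   = par["timestep"];
  const double gamma = par["friction"];
  const double temp = par["temperature"];
  const double mass = par["mass"];
  const double nsteps_d = par["n_steps"];
  const long long nsteps = (long long) nsteps_d;
  const int stride = par["output_stride"];
  const int seed = par["seed"];
  const double kT = KB * temp;
  const double dh_pref = par["dh_prefactor"];
  const double lD = par["debye_length"];
  const double elec_cut = par["elec_cutoff"];
  const double ev_cut = par["ev_cutoff"];
  const double ev_eps = par["excluded_epsilon"];
  const double bond_k = par["bond_k"];
  const double angle_k = par["angle_k"];
  const double tether_k = par["tether_k"];
  const double tether_r0 = par["tether_r0"];
  const double restraint_k = par["restraint_k"];
  const double box_bound = par["box_bound"];
  const double skin = 0.6;
  const double list_cut = std::max(elec_cut, ev_cut) + skin;
  const double list_cut2 = list_cut * list_cut;
  // per-pair cutoff is min(ev_cut, 2 sigma_ij); at 2 sigma the shift is
  // eps/2^12, used whenever the 2-sigma cutoff is the active one
  const double ev_shift_2sig = ev_eps / 4096.0;

  std::vector<Vec> x(n), xref(n), v(n, {0, 0, 0}), f(n);
  for (int i = 0; i < n; ++i) {
    x[i] = {pos0(i, 0), pos0(i, 1), pos0(i, 2)};
    xref[i] = x[i];
  }
  Vec center0 = {0, 0, 0};
  for (int i = 0; i < n; ++i) {
    center0.x += x[i].x / n; center0.y += x[i].y / n; center0.z += x[i].z / n;
  }

  std::mt19937_64 rng(seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  const double c1 = std::exp(-gamma * dt);
  const double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));

  const int ncand = cand_i.size();
  std::vector<int> nl_i, nl_j; std::vector<char> nl_ev;
  std::vector<double> nl_qq, nl_sig;
  std::vector<Vec> x_at_build(n);
  long long n_rebuilds = 0;
  auto build_list = [&]() {
    ++n_rebuilds;
    nl_i.clear(); nl_j.clear(); nl_ev.clear(); nl_qq.clear();
    nl_sig.clear();
    for (int k = 0; k < ncand; ++k) {
      int i = cand_i[k], j = cand_j[k];
      double dx = x[i].x - x[j].x, dy = x[i].y - x[j].y,
             dz = x[i].z - x[j].z;
      if (dx * dx + dy * dy + dz * dz < list_cut2) {
        nl_i.push_back(i); nl_j.push_back(j);
        nl_ev.push_back(cand_ev[k] ? 1 : 0);
        nl_qq.push_back(charge[i] * charge[j]);
        nl_sig.push_back(0.5 * (sigma_bead[i] + sigma_bead[j]));
      }
    }
    x_at_build = x;
  };
  auto need_rebuild = [&]() {
    double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = x[i].x - x_at_build[i].x, dy = x[i].y - x_at_build[i].y,
             dz = x[i].z - x_at_build[i].z;
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  };

  // energy components: 0 bonded, 1 angle, 2 native, 3 elec, 4 ev,
  // 5 restraint, 6 tether
  std::vector<double> ecomp(7, 0.0);
  auto compute_forces = [&](bool want_energy) {
    for (int i = 0; i < n; ++i) f[i] = {0, 0, 0};
    if (want_energy) std::fill(ecomp.begin(), ecomp.end(), 0.0);
    // bonds
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0), j = bonds(b, 1);
      double dx = x[i].x - x[j].x, dy = x[i].y - x[j].y,
             dz = x[i].z - x[j].z;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dU = bond_k * (r - bond_r0[b]);
      double c = -dU / r;
      f[i].x += c * dx; f[i].y += c * dy; f[i].z += c * dz;
      f[j].x -= c * dx; f[j].y -= c * dy; f[j].z -= c * dz;
      if (want_energy)
        ecomp[0] += 0.5 * bond_k * (r - bond_r0[b]) * (r - bond_r0[b]);
    }
    // angles
    for (int a = 0; a < angles.nrow(); ++a) {
      int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
      double v1x = x[i].x - x[j].x, v1y = x[i].y - x[j].y,
             v1z = x[i].z - x[j].z;
      double v2x = x[k].x - x[j].x, v2y = x[k].y - x[j].y,
             v2z = x[k].z - x[j].z;
      double r1 = std::sqrt(v1x * v1x + v1y * v1y + v1z * v1z);
      double r2 = std::sqrt(v2x * v2x + v2y * v2y + v2z * v2z);
      double cth = (v1x * v2x + v1y * v2y + v1z * v2z) / (r1 * r2);
      cth = std::max(-1.0, std::min(1.0, cth));
      double th = std::acos(cth);
      double s = std::sqrt(std::max(1e-12, 1.0 - cth * cth));
      double dU = angle_k * (th - angle_th0[a]);
      // dtheta/dxi etc.
      double ax = (v2x / (r1 * r2) - cth * v1x / (r1 * r1)) / -s;
      double ay = (v2y / (r1 * r2) - cth * v1y / (r1 * r1)) / -s;
      double az = (v2z / (r1 * r2) - cth * v1z / (r1 * r1)) / -s;
      double cx = (v1x / (r1 * r2) - cth * v2x / (r2 * r2)) / -s;
      double cy = (v1y / (r1 * r2) - cth * v2y / (r2 * r2)) / -s;
      double cz = (v1z / (r1 * r2) - cth * v2z / (r2 * r2)) / -s;
      f[i].x -= dU * ax; f[i].y -= dU * ay; f[i].z -= dU * az;
      f[k].x -= dU * cx; f[k].y -= dU * cy; f[k].z -= dU * cz;
      f[j].x += dU * (ax + cx); f[j].y += dU * (ay + cy);
      f[j].z += dU * (az + cz);
      if (want_energy)
        ecomp[1] += 0.5 * angle_k * (th - angle_th0[a]) * (th - angle_th0[a]);
    }
    // native contacts (12-10 Go)
    for (int c0 = 0; c0 < contacts.nrow(); ++c0) {
      int i = contacts(c0, 0), j = contacts(c0, 1);
      double dx = x[i].x - x[j].x, dy = x[i].y - x[j].y,
             dz = x[i].z - x[j].z;
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      double s2 = contact_r0[c0] * contact_r0[c0] / r2;
      double s10 = s2 * s2 * s2 * s2 * s2;
      double s12 = s10 * s2;
      double eps = contact_eps[c0];
      double dU = 60.0 * eps * (s10 - s12) / r;
      double c = -dU / r;
      f[i].x += c * dx; f[i].y += c * dy; f[i].z += c * dz;
      f[j].x -= c * dx; f[j].y -= c * dy; f[j].z -= c * dz;
      if (want_energy) ecomp[2] += eps * (5.0 * s12 - 6.0 * s10);
    }
    // tethers
    for (int t = 0; t < tethers.nrow(); ++t) {
      int i = tethers(t, 0), j = tethers(t, 1);
      double dx = x[i].x - x[j].x, dy = x[i].y - x[j].y,
             dz = x[i].z - x[j].z;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r <= tether_r0) continue;   // slack flat-bottom linker
      double dU = tether_k * (r - tether_r0);
      double c = -dU / r;
      f[i].x += c * dx; f[i].y += c * dy; f[i].z += c * dz;
      f[j].x -= c * dx; f[j].y -= c * dy; f[j].z -= c * dz;
      if (want_energy)
        ecomp[6] += 0.5 * tether_k * (r - tether_r0) * (r - tether_r0);
    }
    // restraints
    if (restraint_k > 0) {
      for (int i = 0; i < n; ++i) {
        if (!anchored[i]) continue;
        double dx = x[i].x - xref[i].x, dy = x[i].y - xref[i].y,
               dz = x[i].z - xref[i].z;
        f[i].x -= restraint_k * dx; f[i].y -= restraint_k * dy;
        f[i].z -= restraint_k * dz;
        if (want_energy)
          ecomp[5] += 0.5 * restraint_k * (dx * dx + dy * dy + dz * dz);
      }
    }
    // nonbonded from neighbour list
    const size_t m = nl_i.size();
    for (size_t p = 0; p < m; ++p) {
      int i = nl_i[p], j = nl_j[p];
      double dx = x[i].x - x[j].x, dy = x[i].y - x[j].y,
             dz = x[i].z - x[j].z;
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      double dU = 0.0;
      if (nl_qq[p] != 0.0 && r < elec_cut) {
        double u = dh_pref * nl_qq[p] * std::exp(-r / lD) / r;
        dU += -u * (1.0 / lD + 1.0 / r);
        if (want_energy) ecomp[3] += u;
      }
      double cut_p = std::min(ev_cut, 2.0 * nl_sig[p]);
      if (nl_ev[p] && r < cut_p) {
        double sr = nl_sig[p] / r;
        double sr2 = sr * sr;
        double sr12 = sr2 * sr2 * sr2; sr12 = sr12 * sr12;
        double shift = (cut_p < ev_cut) ? ev_shift_2sig :
          ev_eps * std::pow(nl_sig[p] / ev_cut, 12.0);
        dU += -12.0 * ev_eps * sr12 / r;
        if (want_energy) ecomp[4] += ev_eps * sr12 - shift;
      }
      if (dU != 0.0) {
        double c = -dU / r;
        f[i].x += c * dx; f[i].y += c * dy; f[i].z += c * dz;
        f[j].x -= c * dx; f[j].y -= c * dy; f[j].z -= c * dz;
      }
    }
  };

  // displacement-capped steepest descent to relax steric clashes in the
  // built geometry (e.g. straight-built tails crossing a placed head)
  // before dynamics; anchored beads are held fixed during minimization.
  const int min_steps = par.containsElementNamed("minimize_steps")
      ? (int) as<double>(par["minimize_steps"]) : 0;
  const double min_cap = 0.05;   // nm per bead per iteration
  for (int it = 0; it < min_steps; ++it) {
    if (it % 5 == 0 || need_rebuild()) build_list();
    compute_forces(false);
    for (int i = 0; i < n; ++i) {
      if (anchored[i]) continue;
      double fmag = std::sqrt(f[i].x * f[i].x + f[i].y * f[i].y +
                              f[i].z * f[i].z);
      if (fmag < 1e-12) continue;
      double step_len = std::min(min_cap, 2e-4 * fmag);
      double c = step_len / fmag;
      x[i].x += c * f[i].x; x[i].y += c * f[i].y; x[i].z += c * f[i].z;
    }
  }

  build_list();
  compute_forces(true);
  NumericVector energy0 = NumericVector::create(
      _["bonded"] = ecomp[0], _["angle"] = ecomp[1],
      _["native"] = ecomp[2], _["electrostatic"] = ecomp[3],
      _["excluded"] = ecomp[4], _["restraint"] = ecomp[5],
      _["tether"] = ecomp[6]);

  const long long nframes = nsteps / stride;
  NumericVector steps_out(nframes);
  NumericMatrix com_low(nframes, 3), com_high(nframes, 3);
  NumericVector full;
  if (output_full) {
    full = NumericVector((R_xlen_t) nframes * n * 3);
    full.attr("dim") = IntegerVector::create(nframes, n, 3);
  }
  NumericVector efinal(7);
  int error_frame = -1;
  const double hdt = 0.5 * dt;

  long long frame = 0;
  for (long long step = 1; step <= nsteps; ++step) {
    // BAOAB: B (half kick), A (half drift), O, A, [forces], B
    for (int i = 0; i < n; ++i) {
      v[i].x += hdt * f[i].x / mass;
      v[i].y += hdt * f[i].y / mass;
      v[i].z += hdt * f[i].z / mass;
      x[i].x += hdt * v[i].x; x[i].y += hdt * v[i].y;
      x[i].z += hdt * v[i].z;
    }
    if (gamma > 0 || temp > 0) {
      for (int i = 0; i < n; ++i) {
        v[i].x = c1 * v[i].x + c2 * gauss(rng);
        v[i].y = c1 * v[i].y + c2 * gauss(rng);
        v[i].z = c1 * v[i].z + c2 * gauss(rng);
      }
    }
    for (int i = 0; i < n; ++i) {
      x[i].x += hdt * v[i].x; x[i].y += hdt * v[i].y;
      x[i].z += hdt * v[i].z;
    }
    if (need_rebuild()) build_list();
    bool want_e = (step == nsteps);
    compute_forces(want_e);
    for (int i = 0; i < n; ++i) {
      v[i].x += hdt * f[i].x / mass;
      v[i].y += hdt * f[i].y / mass;
      v[i].z += hdt * f[i].z / mass;
    }
    if (step % stride == 0) {
      Vec cl = {0, 0, 0}, ch = {0, 0, 0};
      for (int t = 0; t < track_low.size(); ++t) {
        int i = track_low[t];
        cl.x += x[i].x; cl.y += x[i].y; cl.z += x[i].z;
      }
      for (int t = 0; t < track_high.size(); ++t) {
        int i = track_high[t];
        ch.x += x[i].x; ch.y += x[i].y; ch.z += x[i].z;
      }
      int nl0 = std::max(1, (int) track_low.size());
      int nh0 = std::max(1, (int) track_high.size());
      steps_out[frame] = (double) step;
      com_low(frame, 0) = cl.x / nl0; com_low(frame, 1) = cl.y / nl0;
      com_low(frame, 2) = cl.z / nl0;
      com_high(frame, 0) = ch.x / nh0; com_high(frame, 1) = ch.y / nh0;
      com_high(frame, 2) = ch.z / nh0;
      if (output_full) {
        for (int i = 0; i < n; ++i) {
          full[frame + (R_xlen_t) nframes * i] = x[i].x;
          full[frame + (R_xlen_t) nframes * (n + i)] = x[i].y;
          full[frame + (R_xlen_t) nframes * (2 * n + i)] = x[i].z;
        }
      }
      bool blown = false;
      for (int i = 0; i < n && !blown; ++i) {
        double dx = x[i].x - center0.x, dy = x[i].y - center0.y,
               dz = x[i].z - center0.z;
        if (!std::isfinite(x[i].x) || !std::isfinite(x[i].y) ||
            !std::isfinite(x[i].z) ||
            std::fabs(dx) > box_bound || std::fabs(dy) > box_bound ||
            std::fabs(dz) > box_bound)
          blown = true;
      }
      if (blown) { error_frame = (int) frame + 1; break; }
      ++frame;
    }
  }
  for (int k = 0; k < 7; ++k) efinal[k] = ecomp[k];
  double ekin = 0.0;
  for (int i = 0; i < n; ++i)
    ekin += 0.5 * mass *
      (v[i].x * v[i].x + v[i].y * v[i].y + v[i].z * v[i].z);
  return List::create(
      _["steps"] = steps_out, _["com_low"] = com_low,
      _["com_high"] = com_high, _["full"] = full,
      _["energy0"] = energy0, _["energy_final"] = efinal,
      _["kinetic_final"] = ekin, _["n_rebuilds"] = (double) n_rebuilds,
      _["n_frames"] = (double) frame, _["error_frame"] = error_frame);
}
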