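// Structure-based coarse-grained force field and Langevin propagator.
//
// Energy terms (kcal/mol, lengths in Angstrom):
//   bonds      E = k (r - r0)^2
//   angles     E = k (theta - theta0)^2
//   dihedrals  E = k [(1 - cos(d)) + 0.5 (1 - cos(3 d))], d = phi - phi0
//              (or harmonic k d^2 with d wrapped to (-pi, pi])
//   contacts   E = k [5 (a/r)^12 - 6 (a/r)^10]   (minimum -k at r = a)
//   excl. vol. E = k (sigma/r)^12                (truncated at 3 sigma)
//   electro    E = Kc B(kappa) qi qj exp(-kappa r) / (eps r)
//
// The propagator is the BAOAB splitting of underdamped Langevin dynamics
// (one force evaluation per step; exact Ornstein-Uhlenbeck O-step; reduces
// to velocity Verlet when gamma = 0).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double EV_TRUNC2 = 9.0; // EV truncated at r > 3 sigma ((r/sigma)^2 > 9)

struct Terms {
  IntegerVector bi, bj;             NumericVector b_x0, b_k;
  IntegerVector ai, aj, ak;         NumericVector a_x0, a_k;
  IntegerVector di, dj, dk, dl;     NumericVector d_x0, d_k;
  IntegerVector ci, cj;             NumericVector c_a, c_k;
  IntegerVector ei, ej;             NumericVector e_sigma;
  IntegerVector qi, qj;             NumericVector e_qq;
  double k_ev, k_coul_eff, kappa, elec_cutoff; // k_coul_eff = Kc * B / eps
  int dihedral_form;                            // 0 cosine series, 1 harmonic
};

static Terms unpack_terms(const List& ff) {
  Terms t;
  t.bi = ff["bond_i"];  t.bj = ff["bond_j"];
  t.b_x0 = ff["bond_x0"]; t.b_k = ff["bond_k"];
  t.ai = ff["angle_i"]; t.aj = ff["angle_j"]; t.ak = ff["angle_k"];
  t.a_x0 = ff["angle_x0"]; t.a_k = ff["angle_kf"];
  t.di = ff["dih_i"]; t.dj = ff["dih_j"]; t.dk = ff["dih_k"]; t.dl = ff["dih_l"];
  t.d_x0 = ff["dih_x0"]; t.d_k = ff["dih_kf"];
  t.ci = ff["con_i"]; t.cj = ff["con_j"];
  t.c_a = ff["con_a"]; t.c_k = ff["con_kf"];
  t.ei = ff["ev_i"]; t.ej = ff["ev_j"]; t.e_sigma = ff["ev_sigma"];
  t.qi = ff["el_i"]; t.qj = ff["el_j"]; t.e_qq = ff["el_qq"];
  t.k_ev = as<double>(ff["k_ev"]);
  t.k_coul_eff = as<double>(ff["k_coul_eff"]);
  t.kappa = as<double>(ff["kappa"]);
  t.elec_cutoff = as<double>(ff["elec_cutoff"]);
  t.dihedral_form = as<int>(ff["dihedral_form"]);
  return t;
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double wrap_pi(double a) {
  return a - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
}

// Evaluate energy and (optionally) forces. xyz is n x 3 (row-major access
// through pointers); frc accumulates -dE/dx if not null.
static void eval_ff(const Terms& t, const double* x, const double* y,
                    const double* z, int n, double* fx, double* fy, double* fz,
                    double* e_out /* 6 components */) {
  double e_bond = 0, e_angle = 0, e_dih = 0, e_con = 0, e_ev = 0, e_el = 0;
  const bool wantf = fx != nullptr;

  // bonds
  for (int m = 0; m < t.bi.size(); ++m) {
    int i = t.bi[m], j = t.bj[m];
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r <= 0) stop("overlapping beads in bond term (%d, %d)", i + 1, j + 1);
    double dr = r - t.b_x0[m];
    e_bond += t.b_k[m] * dr * dr;
    if (wantf) {
      double g = 2.0 * t.b_k[m] * dr / r; // dE/dr / r
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
    }
  }

  // angles
  for (int m = 0; m < t.ai.size(); ++m) {
    int i = t.ai[m], j = t.aj[m], k = t.ak[m];
    double u[3] = {x[i] - x[j], y[i] - y[j], z[i] - z[j]};
    double v[3] = {x[k] - x[j], y[k] - y[j], z[k] - z[j]};
    double lu = std::sqrt(dot3(u, u)), lv = std::sqrt(dot3(v, v));
    if (lu <= 0 || lv <= 0) stop("overlapping beads in angle term");
    double c = dot3(u, v) / (lu * lv);
    if (c > 1) c = 1;
    if (c < -1) c = -1;
    double th = std::acos(c);
    double dth = th - t.a_x0[m];
    e_angle += t.a_k[m] * dth * dth;
    if (wantf) {
      double s = std::sqrt(1.0 - c * c);
      if (s < 1e-8) continue; // colinear: gradient direction degenerate
      double dEdth = 2.0 * t.a_k[m] * dth;
      double gi[3], gk[3];
      for (int q = 0; q < 3; ++q) {
        gi[q] = (c * u[q] / lu - v[q] / lv) / (lu * s);
        gk[q] = (c * v[q] / lv - u[q] / lu) / (lv * s);
      }
      fx[i] -= dEdth * gi[0]; fy[i] -= dEdth * gi[1]; fz[i] -= dEdth * gi[2];
      fx[k] -= dEdth * gk[0]; fy[k] -= dEdth * gk[1]; fz[k] -= dEdth * gk[2];
      fx[j] += dEdth * (gi[0] + gk[0]);
      fy[j] += dEdth * (gi[1] + gk[1]);
      fz[j] += dEdth * (gi[2] + gk[2]);
    }
  }

  // dihedrals
  for (int m = 0; m < t.di.size(); ++m) {
    int i = t.di[m], j = t.dj[m], k = t.dk[m], l = t.dl[m];
    double km = t.d_k[m];
    if (km == 0) continue;
    double b1[3] = {x[j] - x[i], y[j] - y[i], z[j] - z[i]};
    double b2[3] = {x[k] - x[j], y[k] - y[j], z[k] - z[j]};
    double b3[3] = {x[l] - x[k], y[l] - y[k], z[l] - z[k]};
    double n1[3], n2[3], m1[3];
    cross3(b1, b2, n1);
    cross3(b2, b3, n2);
    cross3(n1, b2, m1);
    double lb2 = std::sqrt(dot3(b2, b2));
    if (lb2 <= 0) stop("overlapping beads in dihedral term");
    double phi = std::atan2(dot3(m1, n2) / lb2, dot3(n1, n2));
    double d = phi - t.d_x0[m];
    double dEdphi;
    if (t.dihedral_form == 0) {
      e_dih += km * ((1.0 - std::cos(d)) + 0.5 * (1.0 - std::cos(3.0 * d)));
      dEdphi = km * (std::sin(d) + 1.5 * std::sin(3.0 * d));
    } else {
      double dw = wrap_pi(d);
      e_dih += km * dw * dw;
      dEdphi = 2.0 * km * dw;
    }
    if (wantf) {
      double n1sq = dot3(n1, n1), n2sq = dot3(n2, n2);
      if (n1sq < 1e-12 || n2sq < 1e-12) continue; // colinear chain segment
      // gradient of phi w.r.t. the four bead positions
      double dpi[3], dpl[3], dpj[3], dpk[3];
      double p = dot3(b1, b2) / (lb2 * lb2);
      double qq = dot3(b3, b2) / (lb2 * lb2);
      for (int q = 0; q < 3; ++q) {
        dpi[q] = lb2 / n1sq * n1[q];
        dpl[q] = -lb2 / n2sq * n2[q];
        dpj[q] = -(1.0 + p) * dpi[q] + qq * dpl[q];
        dpk[q] = p * dpi[q] - (1.0 + qq) * dpl[q];
      }
      fx[i] -= dEdphi * dpi[0]; fy[i] -= dEdphi * dpi[1]; fz[i] -= dEdphi * dpi[2];
      fx[j] -= dEdphi * dpj[0]; fy[j] -= dEdphi * dpj[1]; fz[j] -= dEdphi * dpj[2];
      fx[k] -= dEdphi * dpk[0]; fy[k] -= dEdphi * dpk[1]; fz[k] -= dEdphi * dpk[2];
      fx[l] -= dEdphi * dpl[0]; fy[l] -= dEdphi * dpl[1]; fz[l] -= dEdphi * dpl[2];
    }
  }

  // 12-10 native contacts (and target-site terms)
  for (int m = 0; m < t.ci.size(); ++m) {
    int i = t.ci[m], j = t.cj[m];
    double km = t.c_k[m];
    if (km == 0) continue;
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 <= 0) stop("overlapping beads in contact term (%d, %d)", i + 1, j + 1);
    double a2 = t.c_a[m] * t.c_a[m];
    double s2 = a2 / r2;
    double s10 = s2 * s2 * s2 * s2 * s2;
    double s12 = s10 * s2;
    e_con += km * (5.0 * s12 - 6.0 * s10);
    if (wantf) {
      double g = km * 60.0 * (s12 - s10) / r2; // -dE/dr / r
      fx[i] -= g * dx; fy[i] -= g * dy; fz[i] -= g * dz;
      fx[j] += g * dx; fy[j] += g * dy; fz[j] += g * dz;
    }
  }

  // excluded volume
  for (int m = 0; m < t.ei.size(); ++m) {
    int i = t.ei[m], j = t.ej[m];
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    double s = t.e_sigma[m];
    if (r2 > s * s * EV_TRUNC2) continue;
    if (r2 <= 0) stop("overlapping beads in excluded-volume pair (%d, %d)",
                      i + 1, j + 1);
    double s2 = s * s / r2;
    double s12 = s2 * s2 * s2 * s2 * s2 * s2;
    e_ev += t.k_ev * s12;
    if (wantf) {
      double g = t.k_ev * 12.0 * s12 / r2; // -dE/dr / r
      fx[i] -= g * dx; fy[i] -= g * dy; fz[i] -= g * dz;
      fx[j] += g * dx; fy[j] += g * dy; fz[j] += g * dz;
    }
  }

  // Debye-Hueckel electrostatics
  double rc2 = t.elec_cutoff > 0 ? t.elec_cutoff * t.elec_cutoff : -1.0;
  for (int m = 0; m < t.qi.size(); ++m) {
    int i = t.qi[m], j = t.qj[m];
    double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (rc2 > 0 && r2 > rc2) continue;
    if (r2 <= 0) stop("overlapping charged beads (%d, %d)", i + 1, j + 1);
    double r = std::sqrt(r2);
    double e = t.k_coul_eff * t.e_qq[m] * std::exp(-t.kappa * r) / r;
    e_el += e;
    if (rc2 > 0) // shift so the energy is continuous at the cutoff
      e_el -= t.k_coul_eff * t.e_qq[m] * std::exp(-t.kappa * t.elec_cutoff) /
              t.elec_cutoff;
    if (wantf) {
      double g = -e * (t.kappa + 1.0 / r) / r; // dE/dr / r
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
    }
  }

  e_out[0] = e_bond; e_out[1] = e_angle; e_out[2] = e_dih;
  e_out[3] = e_con; e_out[4] = e_ev; e_out[5] = e_el;
}

// [[Rcpp::export(name = ".cg_energy_forces")]]
List cg_energy_forces(NumericMatrix xyz, List ff, bool forces = true) {
  int n = xyz.nrow();
  std::vector<double> x(n), y(n), z(n), fx, fy, fz;
  for (int i = 0; i < n; ++i) { x[i] = xyz(i, 0); y[i] = xyz(i, 1); z[i] = xyz(i, 2); }
  double e[6];
  NumericMatrix f(n, 3);
  if (forces) {
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
  }
  Terms t = unpack_terms(ff);
  eval_ff(t, x.data(), y.data(), z.data(), n,
          forces ? fx.data() : nullptr, forces ? fy.data() : nullptr,
          forces ? fz.data() : nullptr, e);
  if (forces)
    for (int i = 0; i < n; ++i) { f(i, 0) = fx[i]; f(i, 1) = fy[i]; f(i, 2) = fz[i]; }
  return List::create(
    _["bond"] = e[0], _["angle"] = e[1], _["dihedral"] = e[2],
    _["contact"] = e[3], _["excluded_volume"] = e[4],
    _["electrostatic"] = e[5],
    _["total"] = e[0] + e[1] + e[2] + e[3] + e[4] + e[5],
    _["forces"] = forces ? (SEXP)f : R_NilValue);
}

// BAOAB Langevin propagation. Uses R's RNG stream (seed with set.seed()).
// [[Rcpp::export(name = ".cg_run_langevin")]]
List cg_run_langevin(NumericMatrix xyz0, NumericMatrix vel0, List ff,
                     LogicalVector movable, NumericVector box_lo,
                     NumericVector box_hi, int n_steps, double dt,
                     double gamma, double kT, int save_interval,
                     double mass = 1.0) {
  int n = xyz0.nrow();
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = xyz0(i, 0); y[i] = xyz0(i, 1); z[i] = xyz0(i, 2);
    vx[i] = vel0(i, 0); vy[i] = vel0(i, 1); vz[i] = vel0(i, 2);
  }
  Terms t = unpack_terms(ff);
  double e[6];

  int n_frames = n_steps / std::max(save_interval, 1) + 1;
  NumericVector frames((R_xlen_t)n_frames * n * 3);
  NumericMatrix energies(n_frames, 8);
  int frame = 0;
  auto save_frame = [&](int fr) {
    R_xlen_t off = (R_xlen_t)fr * n * 3;
    double ekin = 0;
    for (int i = 0; i < n; ++i) {
      frames[off + i] = x[i];
      frames[off + n + i] = y[i];
      frames[off + 2 * n + i] = z[i];
      if (movable[i])
        ekin += 0.5 * mass * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
    }
    for (int q = 0; q < 6; ++q) energies(fr, q) = e[q];
    energies(fr, 6) = e[0] + e[1] + e[2] + e[3] + e[4] + e[5];
    energies(fr, 7) = ekin;
  };

  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(kT / mass * (1.0 - c1 * c1));
  double half_dt = 0.5 * dt;

  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  eval_ff(t, x.data(), y.data(), z.data(), n, fx.data(), fy.data(), fz.data(), e);
  save_frame(frame++);

  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      if (!movable[i]) continue;
      // B
      vx[i] += half_dt * fx[i] / mass;
      vy[i] += half_dt * fy[i] / mass;
      vz[i] += half_dt * fz[i] / mass;
      // A
      x[i] += half_dt * vx[i];
      y[i] += half_dt * vy[i];
      z[i] += half_dt * vz[i];
      // O
      if (gamma > 0) {
        vx[i] = c1 * vx[i] + c2 * norm_rand();
        vy[i] = c1 * vy[i] + c2 * norm_rand();
        vz[i] = c1 * vz[i] + c2 * norm_rand();
      }
      // A
      x[i] += half_dt * vx[i];
      y[i] += half_dt * vy[i];
      z[i] += half_dt * vz[i];
      // reflecting walls
      double* pos[3] = {&x[i], &y[i], &z[i]};
      double* vel[3] = {&vx[i], &vy[i], &vz[i]};
      for (int q = 0; q < 3; ++q) {
        if (*pos[q] < box_lo[q]) { *pos[q] = 2 * box_lo[q] - *pos[q]; *vel[q] = -*vel[q]; }
        else if (*pos[q] > box_hi[q]) { *pos[q] = 2 * box_hi[q] - *pos[q]; *vel[q] = -*vel[q]; }
        if (*pos[q] < box_lo[q] - 10.0 || *pos[q] > box_hi[q] + 10.0)
          stop("bead %d escaped the box by more than 10 A at step %d", i + 1, step);
      }
    }
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    eval_ff(t, x.data(), y.data(), z.data(), n, fx.data(), fy.data(), fz.data(), e);
    for (int i = 0; i < n; ++i) {
      if (!movable[i]) continue;
      vx[i] += half_dt * fx[i] / mass;
      vy[i] += half_dt * fy[i] / mass;
      vz[i] += half_dt * fz[i] / mass;
      if (!std::isfinite(x[i]) || !std::isfinite(fx[i]) ||
          !std::isfinite(y[i]) || !std::isfinite(fy[i]) ||
          !std::isfinite(z[i]) || !std::isfinite(fz[i]))
        stop("non-finite position or force on bead %d at step %d", i + 1, step);
    }
    if (save_interval > 0 && step % save_interval == 0 && frame < n_frames)
      save_frame(frame++);
  }

  NumericMatrix xyz_out(n, 3), vel_out(n, 3);
  for (int i = 0; i < n; ++i) {
    xyz_out(i, 0) = x[i]; xyz_out(i, 1) = y[i]; xyz_out(i, 2) = z[i];
    vel_out(i, 0) = vx[i]; vel_out(i, 1) = vy[i]; vel_out(i, 2) = vz[i];
  }
  frames.attr("dim") = IntegerVector::create(n, 3, n_frames);
  return List::create(_["frames"] = frames, _["energies"] = energies,
                      _["positions"] = xyz_out, _["velocities"] = vel_out,
                      _["n_frames"] = frame);
}
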