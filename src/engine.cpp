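// Core numerics for the reduced-dimensional biliverdin photoisomerization model:
// diabatic/adiabatic surfaces with analytic gradients, ground-state Langevin/CSVR
// sampling, and the fewest-switches surface-hopping propagator with
// local-diabatization electronic integration and energy-based decoherence.
//
// Internal units: kcal/mol, amu, Angstrom, fs, radians. Angles cross the R
// interface in degrees and are converted here.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// 1 amu * A^2 / fs^2 in kcal/mol
static const double KCAL_PER_AMU_A2_FS2 = 2390.0574;
// hbar in kcal/mol * fs
static const double HBAR = 15.17873;
// Boltzmann constant, kcal/mol/K
static const double KB = 0.0019872041;
static const double DEG = M_PI / 180.0;
// 1 eV in kcal/mol
static const double EV = 23.0609;

// ---------------------------------------------------------------------------
// Deterministic RNG (xorshift-free: splitmix64 -> mt19937_64 seeding is
// platform stable; normals via Box-Muller so streams are bit reproducible).
struct RNG {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit RNG(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() { // xoshiro256++
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
struct Params {
  double E_vert, V6_S1, V6_S0, V5, chi;
  double theta6_CI, w0, sigma_w;       // coupling Gaussian (deg -> rad below)
  double D_hb, a_hb, r0_hb, lambda_hb; // H-bond Morse + planarity coupling
  double theta_off;                    // S0 D6 offset released at weak H-bond (rad)
  double w_cw;                         // clockwise wall amplitude
  double k_cage, r_cage;               // pocket cage on r_hb
  double h_strain, theta_strain, sigma_strain; // pocket strain ridge (common)
  double s6;                           // S1 torsional amplitude scale
  double I6, I5, m_r;                  // inertias (amu A^2) and mass (amu)
  double gamma_s1, T_s1, gamma_s0, T;  // SH-stage baths (1/fs internally, K)
};

static Params paramsFromList(const List &p) {
  Params q;
  q.E_vert = as<double>(p["E_vert"]);
  q.V6_S1 = as<double>(p["V6_S1"]);
  q.V6_S0 = as<double>(p["V6_S0"]);
  q.V5 = as<double>(p["V5"]);
  q.chi = as<double>(p["chi"]);
  q.theta6_CI = as<double>(p["theta6_CI"]) * DEG;
  q.w0 = as<double>(p["w0"]);
  q.sigma_w = as<double>(p["sigma_w"]) * DEG;
  q.D_hb = as<double>(p["D_hb"]);
  q.a_hb = as<double>(p["a_hb"]);
  q.r0_hb = as<double>(p["r0_hb"]);
  q.lambda_hb = as<double>(p["lambda_hb"]);
  q.theta_off = as<double>(p["theta_off"]) * DEG;
  q.w_cw = as<double>(p["w_cw"]);
  q.k_cage = as<double>(p["k_cage"]);
  q.r_cage = as<double>(p["r_cage"]);
  q.h_strain = as<double>(p["h_strain"]);
  q.theta_strain = as<double>(p["theta_strain"]) * DEG;
  q.sigma_strain = as<double>(p["sigma_strain"]) * DEG;
  q.s6 = as<double>(p["s6"]);
  q.I6 = as<double>(p["I6"]);
  q.I5 = as<double>(p["I5"]);
  q.m_r = as<double>(p["m_r"]);
  q.gamma_s1 = as<double>(p["gamma_s1"]) * 1e-3; // ps^-1 -> fs^-1
  q.T_s1 = as<double>(p["T_s1"]);
  q.gamma_s0 = as<double>(p["gamma_s0"]) * 1e-3;
  q.T = as<double>(p["T"]);
  return q;
}

static inline double wrap_pi(double th) {
  // principal branch (-pi, pi]; floor-based to avoid libm fmod
  th -= 2.0 * M_PI * std::floor((th + M_PI) / (2.0 * M_PI));
  if (th <= -M_PI) th += 2.0 * M_PI;      // guard the boundary
  else if (th > M_PI) th -= 2.0 * M_PI;
  return th;
}

// Diabatic matrix elements and analytic gradients wrt (theta6, theta5, r), radians/A.
struct Diab {
  double V11, V22, V12;
  double g11[3], g22[3], g12[3];
};

static void diabatic(const Params &p, double th6in, double th5, double r, Diab &d) {
  const double th6 = wrap_pi(th6in);
  const double x = p.a_hb * (r - p.r0_hb);
  const double ex = std::exp(-x);
  const double mu = 2.0 * ex - ex * ex;          // Morse binding profile, <= 1
  const double dmu = p.a_hb * (-2.0 * ex + 2.0 * ex * ex);
  const double s6c = std::sin(th6), c6 = std::cos(th6);
  const double s5 = std::sin(th5), c5 = std::cos(th5);

  // shared terms (both diabats)
  const double t5 = p.V5 * s5 * s5;
  const double dt5_5 = 2.0 * p.V5 * s5 * c5;
  const double hula = p.chi * s6c * s5;
  const double dhula_6 = p.chi * c6 * s5;
  const double dhula_5 = p.chi * s6c * c5;
  const double cage = 0.5 * p.k_cage * (r - p.r_cage) * (r - p.r_cage);
  const double dcage = p.k_cage * (r - p.r_cage);
  const double rep = 50.0 * std::exp(-8.0 * (r - 0.8));
  const double drep = -8.0 * rep;
  // pocket strain ridge: steric resistance of the tight pocket to the
  // mid-rotation D-ring swing; identical on both diabats, so it shifts the
  // mean surface (guarding the product side of S0) without moving the seam
  const double us = (th6 - p.theta_strain) / p.sigma_strain;
  const double strain = p.h_strain * std::exp(-0.5 * us * us);
  const double dstrain = -strain * us / p.sigma_strain;

  // ground/reactant diabat: D6 torsion rising monotonically toward the
  // product geometry, with an H-bond-controlled planarity offset, + Morse
  const double delta = p.theta_off * (1.0 - mu);
  const double ddelta_r = -p.theta_off * dmu;
  const double sd = std::sin(th6 - delta), cd = std::cos(th6 - delta);
  const double morse = -p.D_hb * mu;
  const double dmorse = -p.D_hb * dmu;
  d.V11 = 0.5 * p.V6_S0 * (1.0 - cd) + morse + t5 + hula + cage + rep + strain;
  d.g11[0] = 0.5 * p.V6_S0 * sd + dhula_6 + dstrain;
  d.g11[1] = dt5_5 + dhula_5;
  d.g11[2] = -0.5 * p.V6_S0 * sd * ddelta_r + dmorse + dcage + drep;

  // excited/product diabat: E_vert, torsional drive toward the product well,
  // clockwise wall, and the H-bond planarity stabilization of the
  // Franck-Condon region (factor ((1+cos)/2)^2: 1 at the planar reactant,
  // 0 at the rotated product)
  const double sig = 1.0 / (1.0 + std::exp(th6 / (10.0 * DEG))); // ~1 for th6<0
  const double dsig = -sig * (1.0 - sig) / (10.0 * DEG);
  const double wall = p.w_cw * s6c * s6c * sig;
  const double dwall = p.w_cw * (2.0 * s6c * c6 * sig + s6c * s6c * dsig);
  const double uu = 0.5 * (1.0 + c6);
  const double plan = -p.lambda_hb * p.D_hb * mu * uu * uu;
  const double dplan_6 = p.lambda_hb * p.D_hb * mu * uu * s6c;
  const double dplan_r = -p.lambda_hb * p.D_hb * dmu * uu * uu;
  d.V22 = p.E_vert - 0.5 * p.s6 * p.V6_S1 * (1.0 - c6) + wall + plan +
          t5 + hula + cage + rep + strain;
  d.g22[0] = -0.5 * p.s6 * p.V6_S1 * s6c + dwall + dplan_6 + dhula_6 + dstrain;
  d.g22[1] = dt5_5 + dhula_5;
  d.g22[2] = dplan_r + dcage + drep;

  // localized diabatic coupling around the seam
  const double u = (th6 - p.theta6_CI) / p.sigma_w;
  const double g = p.w0 * std::exp(-0.5 * u * u);
  d.V12 = g;
  d.g12[0] = -g * u / p.sigma_w;
  d.g12[1] = 0.0;
  d.g12[2] = 0.0;
}

struct Adiab {
  double E0, E1, phi;       // adiabatic energies, mixing angle
  double g0[3], g1[3];      // gradients
};

static void adiabatic(const Params &p, double th6, double th5, double r, Adiab &a) {
  Diab d;
  diabatic(p, th6, th5, r, d);
  const double m = 0.5 * (d.V11 + d.V22);
  const double dl = 0.5 * (d.V11 - d.V22);
  const double w = d.V12;
  double rad = std::sqrt(dl * dl + w * w);
  a.E0 = m - rad;
  a.E1 = m + rad;
  a.phi = 0.5 * std::atan2(w, dl); // eigenvector rotation angle (mod pi)
  const double rs = (rad > 1e-12) ? rad : 1e-12;
  for (int k = 0; k < 3; ++k) {
    const double gm = 0.5 * (d.g11[k] + d.g22[k]);
    const double gd = 0.5 * (d.g11[k] - d.g22[k]);
    const double grad = (dl * gd + w * d.g12[k]) / rs;
    a.g0[k] = gm - grad;
    a.g1[k] = gm + grad;
  }
}

// [[Rcpp::export]]
List cpp_diabatic(List params, double theta6_deg, double theta5_deg, double r_hb) {
  Params p = paramsFromList(params);
  Diab d;
  diabatic(p, theta6_deg * DEG, theta5_deg * DEG, r_hb, d);
  return List::create(_["V11"] = d.V11, _["V22"] = d.V22, _["V12"] = d.V12);
}

// [[Rcpp::export]]
List cpp_adiabatic(List params, double theta6_deg, double theta5_deg, double r_hb) {
  Params p = paramsFromList(params);
  Adiab a;
  adiabatic(p, theta6_deg * DEG, theta5_deg * DEG, r_hb, a);
  // gradients reported per degree for angles, per A for r
  NumericVector g0 = NumericVector::create(a.g0[0] * DEG, a.g0[1] * DEG, a.g0[2]);
  NumericVector g1 = NumericVector::create(a.g1[0] * DEG, a.g1[1] * DEG, a.g1[2]);
  return List::create(_["E0"] = a.E0, _["E1"] = a.E1, _["gap"] = a.E1 - a.E0,
                      _["mixing_angle"] = a.phi, _["grad0"] = g0, _["grad1"] = g1);
}

// Vectorized adiabatic energies on a set of points (for scans).
// [[Rcpp::export]]
NumericMatrix cpp_adiabatic_grid(List params, NumericVector theta6_deg,
                                 NumericVector theta5_deg, NumericVector r_hb) {
  Params p = paramsFromList(params);
  const int n = theta6_deg.size();
  NumericMatrix out(n, 3);
  Adiab a;
  for (int i = 0; i < n; ++i) {
    adiabatic(p, theta6_deg[i] * DEG, theta5_deg[i] * DEG, r_hb[i], a);
    out(i, 0) = a.E0; out(i, 1) = a.E1; out(i, 2) = a.E1 - a.E0;
  }
  colnames(out) = CharacterVector::create("E0", "E1", "gap");
  return out;
}

// Relax (theta5, r) at fixed theta6 on one adiabat by damped gradient descent
// with backtracking; returns the relaxed energy. Used by the barrier scan.
// [[Rcpp::export]]
NumericVector cpp_relaxed_profile(List params, NumericVector theta6_deg, int state,
                                  double theta5_start_deg, double r_start,
                                  int max_iter = 400, double tol = 1e-9) {
  Params p = paramsFromList(params);
  const int n = theta6_deg.size();
  NumericVector out(n);
  double th5 = theta5_start_deg * DEG, r = r_start;
  Adiab a;
  for (int i = 0; i < n; ++i) {
    const double th6 = theta6_deg[i] * DEG;
    adiabatic(p, th6, th5, r, a);
    double e = (state == 1) ? a.E1 : a.E0;
    for (int it = 0; it < max_iter; ++it) {
      const double *g = (state == 1) ? a.g1 : a.g0;
      double g5 = g[1], gr = g[2];
      double gn = std::sqrt(g5 * g5 + gr * gr);
      if (gn < tol * (1.0 + std::fabs(e))) break;
      double step = 0.02;
      bool ok = false;
      for (int bt = 0; bt < 40; ++bt) {
        double t5n = th5 - step * g5, rn = r - step * gr;
        if (rn < 0.3) rn = 0.3;
        Adiab an;
        adiabatic(p, th6, t5n, rn, an);
        double en = (state == 1) ? an.E1 : an.E0;
        if (en < e - 1e-14) {
          th5 = t5n; r = rn; e = en; a = an; ok = true; break;
        }
        step *= 0.5;
      }
      if (!ok) break;
    }
    out[i] = e;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Ground-state MD on E0: velocity Verlet + Bussi-style stochastic velocity
// rescaling (canonical sampling through velocity rescaling, Nf = 3).
// [[Rcpp::export]]
List cpp_ground_state_md(List params, NumericVector q0, NumericVector p0,
                         double dt, int n_steps, int n_equil, int stride,
                         double tau_thermo_fs, uint64_t seed) {
  Params p = paramsFromList(params);
  RNG rng(seed);
  double q[3] = {q0[0] * DEG, q0[1] * DEG, q0[2]};
  double mass[3] = {p.I6, p.I5, p.m_r};
  // momenta supplied in (amu A^2/ fs) units for angles(rad)/r
  double mom[3] = {p0[0], p0[1], p0[2]};
  const double kT = KB * p.T / KCAL_PER_AMU_A2_FS2; // mech units
  const int Nf = 3;
  Adiab a;
  adiabatic(p, q[0], q[1], q[2], a);
  const int n_rec = (n_steps - n_equil + stride - 1) / stride;
  NumericMatrix frames(n_rec, 8);
  int rec = 0;
  const double c1 = std::exp(-dt / tau_thermo_fs);
  for (int step = 0; step < n_steps; ++step) {
    // CSVR thermostat: rescale kinetic energy toward canonical target
    double K = 0.0;
    for (int k = 0; k < 3; ++k) K += 0.5 * mom[k] * mom[k] / mass[k];
    if (K > 1e-14) {
      double R1 = rng.norm();
      double sum2 = 0.0;
      for (int j = 0; j < Nf - 1; ++j) { double z = rng.norm(); sum2 += z * z; }
      double Kbar = 0.5 * Nf * kT;
      double alpha2 = c1 +
        (1.0 - c1) * Kbar * (R1 * R1 + sum2) / (Nf * K) +
        2.0 * R1 * std::sqrt(c1 * (1.0 - c1) * Kbar / (Nf * K));
      double alpha = std::sqrt(std::max(alpha2, 0.0));
      for (int k = 0; k < 3; ++k) mom[k] *= alpha;
    }
    // velocity Verlet on E0 (forces in kcal/mol -> mech units)
    double f[3];
    for (int k = 0; k < 3; ++k) f[k] = -a.g0[k] / KCAL_PER_AMU_A2_FS2;
    for (int k = 0; k < 3; ++k) mom[k] += 0.5 * dt * f[k];
    for (int k = 0; k < 3; ++k) q[k] += dt * mom[k] / mass[k];
    if (q[2] < 0.3) q[2] = 0.3; // hard floor far inside the repulsion wall
    adiabatic(p, q[0], q[1], q[2], a);
    for (int k = 0; k < 3; ++k) f[k] = -a.g0[k] / KCAL_PER_AMU_A2_FS2;
    for (int k = 0; k < 3; ++k) mom[k] += 0.5 * dt * f[k];
    if (!std::isfinite(a.E0) || std::fabs(a.E0) > 1e6)
      stop("ground-state MD diverged at step %d", step);
    if (step >= n_equil && ((step - n_equil) % stride == 0) && rec < n_rec) {
      double K2 = 0.0;
      for (int k = 0; k < 3; ++k) K2 += 0.5 * mom[k] * mom[k] / mass[k];
      frames(rec, 0) = step * dt;
      frames(rec, 1) = wrap_pi(q[0]) / DEG;
      frames(rec, 2) = wrap_pi(q[1]) / DEG;
      frames(rec, 3) = q[2];
      frames(rec, 4) = mom[0];
      frames(rec, 5) = mom[1];
      frames(rec, 6) = mom[2];
      frames(rec, 7) = a.E0 + K2 * KCAL_PER_AMU_A2_FS2;
      ++rec;
    }
  }
  colnames(frames) = CharacterVector::create(
      "time_fs", "theta6_deg", "theta5_deg", "r_hb_A",
      "p_theta6", "p_theta5", "p_r", "energy_kcal");
  return List::create(_["frames"] = frames);
}

// ---------------------------------------------------------------------------
// Surface hopping.
// Electronic coefficients are propagated by local diabatization: the 2x2
// rotation between successive adiabatic bases (angle dphi) defines the locally
// diabatic frame; the exponential of the averaged Hamiltonian is analytic.

struct ElecState {
  double cr[2], ci[2]; // complex coefficients
};

static inline void ld_step(ElecState &c, double E0a, double E1a, double E0b,
                           double E1b, double dphi, double dt) {
  // overlap/rotation T between bases at t and t+dt
  const double ct = std::cos(dphi), st = std::sin(dphi);
  // H_eff in the t-basis: 0.5*(diag(Ea) + T diag(Eb) T^t)
  // T rows: new basis in old basis; T = [[ct, -st],[st, ct]] acting as u_i(t+dt)
  // expressed in u(t): u0' = ct u0 + st u1 ; u1' = -st u0 + ct u1.
  const double h00 = 0.5 * (E0a + (ct * ct * E0b + st * st * E1b));
  const double h11 = 0.5 * (E1a + (st * st * E0b + ct * ct * E1b));
  const double h01 = 0.5 * (ct * st * (E0b - E1b));
  // exp(-i H dt / hbar) analytic for 2x2 Hermitian (real symmetric) H
  const double am = 0.5 * (h00 + h11);
  const double bz = 0.5 * (h00 - h11);
  const double bx = h01;
  const double w = std::sqrt(bz * bz + bx * bx);
  const double tau = dt / HBAR;
  const double cw = std::cos(w * tau), sw = (w > 1e-300) ? std::sin(w * tau) / w : tau;
  // U = e^{-i am tau} [cw I - i sw (bz sz + bx sx)]
  const double pr = std::cos(am * tau), pi_ = -std::sin(am * tau);
  // M = cw I - i sw (bz sz + bx sx):
  // M00 = cw - i sw bz ; M11 = cw + i sw bz ; M01 = M10 = -i sw bx
  double m00r = cw, m00i = -sw * bz;
  double m11r = cw, m11i = sw * bz;
  double m01r = 0.0, m01i = -sw * bx;
  // apply phase
  auto cmul = [](double ar, double ai, double br, double bi, double &rr, double &ri) {
    rr = ar * br - ai * bi; ri = ar * bi + ai * br;
  };
  double t00r, t00i, t11r, t11i, t01r, t01i;
  cmul(pr, pi_, m00r, m00i, t00r, t00i);
  cmul(pr, pi_, m11r, m11i, t11r, t11i);
  cmul(pr, pi_, m01r, m01i, t01r, t01i);
  // c_tilde = U c
  double a0r = t00r * c.cr[0] - t00i * c.ci[0] + t01r * c.cr[1] - t01i * c.ci[1];
  double a0i = t00r * c.ci[0] + t00i * c.cr[0] + t01r * c.ci[1] + t01i * c.cr[1];
  double a1r = t01r * c.cr[0] - t01i * c.ci[0] + t11r * c.cr[1] - t11i * c.ci[1];
  double a1i = t01r * c.ci[0] + t01i * c.cr[0] + t11r * c.ci[1] + t11i * c.cr[1];
  // transform to the t+dt adiabatic basis: c' = T^t c_tilde
  c.cr[0] = ct * a0r + st * a1r;
  c.ci[0] = ct * a0i + st * a1i;
  c.cr[1] = -st * a0r + ct * a1r;
  c.ci[1] = -st * a0i + ct * a1i;
}

// exported single-step electronic propagation for oracle tests
// [[Rcpp::export]]
NumericMatrix cpp_ld_propagate(NumericVector cre, NumericVector cim,
                               double E0a, double E1a, double E0b, double E1b,
                               double dphi, double dt, int substeps = 1) {
  ElecState c;
  c.cr[0] = cre[0]; c.cr[1] = cre[1];
  c.ci[0] = cim[0]; c.ci[1] = cim[1];
  double f = 1.0 / substeps;
  for (int i = 0; i < substeps; ++i) {
    double t0 = i * f, t1 = (i + 1) * f;
    ld_step(c, E0a + (E0b - E0a) * t0, E1a + (E1b - E1a) * t0,
            E0a + (E0b - E0a) * t1, E1a + (E1b - E1a) * t1,
            dphi * f, dt * f);
  }
  NumericMatrix out(2, 2);
  out(0, 0) = c.cr[0]; out(0, 1) = c.ci[0];
  out(1, 0) = c.cr[1]; out(1, 1) = c.ci[1];
  return out;
}

// [[Rcpp::export]]
List cpp_run_trajectory(List params, NumericVector q0, NumericVector p0,
                        int state0, double dt, double t_max_fs,
                        double decoherence_C, double max_hop_gap_ev,
                        int record_stride, uint64_t seed,
                        double stop_window_fs = 500.0,
                        bool gamma_zero = false) {
  Params p = paramsFromList(params);
  RNG rng(seed);
  double q[3] = {q0[0] * DEG, q0[1] * DEG, q0[2]};
  double mom[3] = {p0[0], p0[1], p0[2]};
  double mass[3] = {p.I6, p.I5, p.m_r};
  int active = state0; // 0 or 1
  ElecState c;
  c.cr[0] = (state0 == 0) ? 1.0 : 0.0; c.ci[0] = 0.0;
  c.cr[1] = (state0 == 1) ? 1.0 : 0.0; c.ci[1] = 0.0;

  Adiab a;
  adiabatic(p, q[0], q[1], q[2], a);
  double phi_prev = a.phi;

  const int n_steps = (int)std::llround(t_max_fs / dt);
  const int n_rec = n_steps / record_stride + 2;
  NumericMatrix rec(n_rec, 8);
  int nrec = 0;
  std::vector<double> hop_t, hop_gap, hop_th6, hop_th5, hop_r;
  std::vector<int> hop_from, hop_to, hop_acc;
  double basin_since = -1.0; // time when current S0 basin dwell started
  int basin_id_prev = -99;
  bool stopped = false;
  double t = 0.0;
  int exit_code = 0; // 0 ok(t_max), 1 stopped-in-well, 2 numerical failure

  auto record = [&](double tt) {
    if (nrec >= n_rec) return;
    rec(nrec, 0) = tt;
    rec(nrec, 1) = wrap_pi(q[0]) / DEG;
    rec(nrec, 2) = wrap_pi(q[1]) / DEG;
    rec(nrec, 3) = q[2];
    rec(nrec, 4) = active;
    rec(nrec, 5) = c.cr[1] * c.cr[1] + c.ci[1] * c.ci[1]; // pop S1
    rec(nrec, 6) = (a.E1 - a.E0) / EV;
    double K = 0.0;
    for (int k = 0; k < 3; ++k) K += 0.5 * mom[k] * mom[k] / mass[k];
    rec(nrec, 7) = ((active == 1) ? a.E1 : a.E0) + K * KCAL_PER_AMU_A2_FS2;
    ++nrec;
  };
  record(0.0);

  for (int step = 0; step < n_steps && !stopped; ++step) {
    const double E0a = a.E0, E1a = a.E1;
    // Langevin O-step (state-dependent bath), half at start
    double gamma = (active == 1) ? p.gamma_s1 : p.gamma_s0;
    double Tb = (active == 1) ? p.T_s1 : p.T;
    if (gamma_zero) gamma = 0.0;
    if (gamma > 0.0) {
      const double cg = std::exp(-gamma * 0.5 * dt);
      const double sg = std::sqrt((1.0 - cg * cg) * KB * Tb / KCAL_PER_AMU_A2_FS2);
      for (int k = 0; k < 3; ++k)
        mom[k] = cg * mom[k] + std::sqrt(mass[k]) * sg * rng.norm();
    }
    // velocity Verlet on active surface
    double f[3];
    const double *g = (active == 1) ? a.g1 : a.g0;
    for (int k = 0; k < 3; ++k) f[k] = -g[k] / KCAL_PER_AMU_A2_FS2;
    for (int k = 0; k < 3; ++k) mom[k] += 0.5 * dt * f[k];
    for (int k = 0; k < 3; ++k) q[k] += dt * mom[k] / mass[k];
    if (q[2] < 0.3) q[2] = 0.3;
    adiabatic(p, q[0], q[1], q[2], a);
    if (!std::isfinite(a.E0) || !std::isfinite(a.E1)) { exit_code = 2; break; }
    g = (active == 1) ? a.g1 : a.g0;
    for (int k = 0; k < 3; ++k) f[k] = -g[k] / KCAL_PER_AMU_A2_FS2;
    for (int k = 0; k < 3; ++k) mom[k] += 0.5 * dt * f[k];
    if (gamma > 0.0) {
      const double cg = std::exp(-gamma * 0.5 * dt);
      const double sg = std::sqrt((1.0 - cg * cg) * KB * Tb / KCAL_PER_AMU_A2_FS2);
      for (int k = 0; k < 3; ++k)
        mom[k] = cg * mom[k] + std::sqrt(mass[k]) * sg * rng.norm();
    }
    t = (step + 1) * dt;

    // electronic propagation (local diabatization)
    double dphi = a.phi - phi_prev;
    // eigenvectors are defined modulo pi; keep the branch with |dphi| <= pi/2
    while (dphi > 0.5 * M_PI) dphi -= M_PI;
    while (dphi < -0.5 * M_PI) dphi += M_PI;
    phi_prev = a.phi;
    const double pop_before = c.cr[active] * c.cr[active] + c.ci[active] * c.ci[active];
    ld_step(c, E0a, E1a, a.E0, a.E1, dphi, dt);
    const double pop_after = c.cr[active] * c.cr[active] + c.ci[active] * c.ci[active];

    // fewest-switches hop decision from population flux
    double gprob = 0.0;
    if (pop_before > 1e-12)
      gprob = (pop_before - pop_after) / pop_before;
    if (gprob < 0.0) gprob = 0.0;
    if (gprob > 1.0) gprob = 1.0;
    if (gprob > 0.0 && rng.unif() < gprob) {
      const int target = 1 - active;
      const double gap = a.E1 - a.E0;
      const bool gate_ok = (max_hop_gap_ev <= 0.0) || (gap / EV <= max_hop_gap_ev);
      bool accepted = false;
      if (gate_ok) {
        // rescale along the gradient-difference direction
        double dvec[3];
        for (int k = 0; k < 3; ++k) dvec[k] = a.g1[k] - a.g0[k];
        const double dE = ((target == 1) ? a.E1 : a.E0) -
                          ((active == 1) ? a.E1 : a.E0); // kcal/mol
        double A = 0.0, B = 0.0;
        for (int k = 0; k < 3; ++k) {
          A += 0.5 * dvec[k] * dvec[k] / mass[k];
          B += mom[k] * dvec[k] / mass[k];
        }
        // (1/2m)(p + lam d)^2 = K - dE  =>  A lam^2 + B lam + dE/KCAL = 0
        const double dEm = dE / KCAL_PER_AMU_A2_FS2;
        const double disc = B * B - 4.0 * A * dEm;
        if (disc >= 0.0 && A > 0.0) {
          const double sq = std::sqrt(disc);
          double l1 = (-B + sq) / (2.0 * A), l2 = (-B - sq) / (2.0 * A);
          const double lam = (std::fabs(l1) < std::fabs(l2)) ? l1 : l2;
          for (int k = 0; k < 3; ++k) mom[k] += lam * dvec[k];
          accepted = true;
        }
      }
      hop_t.push_back(t);
      hop_from.push_back(active);
      hop_to.push_back(target);
      hop_gap.push_back(gap / EV);
      hop_th6.push_back(wrap_pi(q[0]) / DEG);
      hop_th5.push_back(wrap_pi(q[1]) / DEG);
      hop_r.push_back(q[2]);
      hop_acc.push_back(accepted ? 1 : 0);
      if (accepted) active = target;
    }

    // energy-based decoherence on the non-active amplitude
    {
      const int j = 1 - active;
      double popj = c.cr[j] * c.cr[j] + c.ci[j] * c.ci[j];
      if (popj > 0.0) {
        double K = 0.0;
        for (int k = 0; k < 3; ++k) K += 0.5 * mom[k] * mom[k] / mass[k];
        double Ekin = K * KCAL_PER_AMU_A2_FS2;
        if (Ekin < 1e-8) Ekin = 1e-8;
        const double dE = std::fabs(a.E1 - a.E0);
        if (dE > 1e-12) {
          const double tau_d = (HBAR / dE) * (1.0 + decoherence_C / Ekin);
          const double damp = std::exp(-dt / tau_d);
          c.cr[j] *= damp; c.ci[j] *= damp;
          const double popa = c.cr[active] * c.cr[active] + c.ci[active] * c.ci[active];
          const double popj2 = c.cr[j] * c.cr[j] + c.ci[j] * c.ci[j];
          if (popa > 1e-300) {
            const double scale = std::sqrt((1.0 - popj2) / popa);
            c.cr[active] *= scale; c.ci[active] *= scale;
          }
        }
      }
    }

    // stop condition: settled on S0 in one torsional basin for stop_window_fs
    if (active == 0) {
      const double th6d = wrap_pi(q[0]) / DEG;
      // reactant basin near 0; product basin near the rotated geometry,
      // which lies at the +-180 wrap point
      int basin = (std::fabs(th6d) < 45.0) ? 0 : ((std::fabs(th6d) > 120.0) ? 1 : -1);
      if (basin >= 0 && basin == basin_id_prev) {
        if (basin_since < 0) basin_since = t;
        else if (t - basin_since >= stop_window_fs) { stopped = true; exit_code = 1; }
      } else {
        basin_since = (basin >= 0) ? t : -1.0;
      }
      basin_id_prev = basin;
    } else {
      basin_id_prev = -99;
      basin_since = -1.0;
    }

    if ((step + 1) % record_stride == 0 || stopped || step == n_steps - 1)
      record(t);
  }

  NumericMatrix series(nrec, 8);
  for (int i = 0; i < nrec; ++i)
    for (int j = 0; j < 8; ++j) series(i, j) = rec(i, j);
  colnames(series) = CharacterVector::create(
      "time_fs", "theta6_deg", "theta5_deg", "r_hb_A",
      "active_state", "pop_S1", "gap_eV", "energy_kcal");
  const int nh = hop_t.size();
  DataFrame hops = DataFrame::create(
      _["time_fs"] = NumericVector(hop_t.begin(), hop_t.end()),
      _["from_state"] = IntegerVector(hop_from.begin(), hop_from.end()),
      _["to_state"] = IntegerVector(hop_to.begin(), hop_to.end()),
      _["gap_eV"] = NumericVector(hop_gap.begin(), hop_gap.end()),
      _["theta6_deg"] = NumericVector(hop_th6.begin(), hop_th6.end()),
      _["theta5_deg"] = NumericVector(hop_th5.begin(), hop_th5.end()),
      _["r_hb_A"] = NumericVector(hop_r.begin(), hop_r.end()),
      _["accepted"] = LogicalVector(hop_acc.begin(), hop_acc.end()));
  return List::create(_["series"] = series, _["hops"] = hops,
                      _["final_state"] = active,
                      _["final_theta6"] = wrap_pi(q[0]) / DEG,
                      _["final_theta5"] = wrap_pi(q[1]) / DEG,
                      _["final_r"] = q[2],
                      _["t_end_fs"] = t, _["exit_code"] = exit_code,
                      _["n_hops"] = nh);
}
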