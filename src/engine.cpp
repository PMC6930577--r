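// Compiled core of the MDOC engine: classical force field, constraint
// observables, tanh-capped pseudo-forces, exponential-memory averaging and
// the velocity-Verlet integration loop. All atom indices arriving here are
// 0-based (R wrappers convert). Units: A, ps, u, kJ/mol throughout.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double F2A = 100.0;   // (kJ mol-1 A-1)/u -> A ps-2
static const double KE2KJ = 0.01;  // u A2 ps-2 -> kJ/mol
static const double KB = 0.008314462618; // kJ mol-1 K-1

struct V3 { double x, y, z; };
static inline V3 v3(double a, double b, double c) { V3 r; r.x = a; r.y = b; r.z = c; return r; }
static inline V3 operator+(V3 a, V3 b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(V3 a, V3 b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, V3 a) { return v3(s * a.x, s * a.y, s * a.z); }
static inline double dot(V3 a, V3 b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(V3 a, V3 b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double nrm(V3 a) { return std::sqrt(dot(a, a)); }
static inline V3 getr(const NumericMatrix& X, int i) { return v3(X(i, 0), X(i, 1), X(i, 2)); }
static inline void addf(NumericMatrix& F, int i, V3 f) {
  F(i, 0) += f.x; F(i, 1) += f.y; F(i, 2) += f.z;
}

// ---------------------------------------------------------------------------
// dihedral angle (IUPAC sign, cis = 0) and its analytic gradient
// ---------------------------------------------------------------------------
static double dihedral(const NumericMatrix& X, int i, int j, int k, int l,
                       V3* g, bool want_grad) {
  V3 b1 = getr(X, j) - getr(X, i);
  V3 b2 = getr(X, k) - getr(X, j);
  V3 b3 = getr(X, l) - getr(X, k);
  V3 m = cross(b1, b2);
  V3 n = cross(b2, b3);
  double lb2 = nrm(b2);
  double m2 = dot(m, m), n2 = dot(n, n);
  if (lb2 < 1e-10 || m2 < 1e-16 || n2 < 1e-16)
    stop("undefined dihedral: collinear atoms along the central bond");
  double y = dot(cross(m, n), (1.0 / lb2) * b2);
  double xx = dot(m, n);
  double phi = std::atan2(y, xx);
  if (want_grad) {
    V3 g1 = (-lb2 / m2) * m;
    V3 g4 = (lb2 / n2) * n;
    double p = dot(b1, b2) / (lb2 * lb2);
    double q = dot(b3, b2) / (lb2 * lb2);
    V3 g2 = (-1.0 - p) * g1 + q * g4;
    V3 g3 = p * g1 + (-1.0 - q) * g4;
    g[0] = g1; g[1] = g2; g[2] = g3; g[3] = g4;
  }
  return phi;
}

// [[Rcpp::export]]
List cpp_dihedral(const NumericMatrix& x, int i, int j, int k, int l, bool grad = false) {
  V3 g[4];
  double phi = dihedral(x, i, j, k, l, g, grad);
  if (!grad) return List::create(_["phi"] = phi);
  NumericMatrix G(4, 3);
  for (int a = 0; a < 4; ++a) { G(a, 0) = g[a].x; G(a, 1) = g[a].y; G(a, 2) = g[a].z; }
  return List::create(_["phi"] = phi, _["grad"] = G);
}

// ---------------------------------------------------------------------------
// classical force field: harmonic bonds/angles, cosine torsions, LJ + Coulomb
// ---------------------------------------------------------------------------
struct Sys {
  int n;
  NumericVector mass;
  IntegerMatrix bonds;   NumericVector bond_r0, bond_k;
  IntegerMatrix angles;  NumericVector ang_th0, ang_k;
  IntegerMatrix tors;    IntegerVector tor_n; NumericVector tor_phase, tor_v;
  IntegerMatrix pairs;   NumericVector pr_sig, pr_eps, pr_qq, pr_scale;
  double cutoff;
};

static Sys unpack_sys(const List& sys) {
  Sys s;
  s.mass = sys["mass"]; s.n = s.mass.size();
  s.bonds = as<IntegerMatrix>(sys["bonds"]);
  s.bond_r0 = sys["bond_r0"]; s.bond_k = sys["bond_k"];
  s.angles = as<IntegerMatrix>(sys["angles"]);
  s.ang_th0 = sys["ang_th0"]; s.ang_k = sys["ang_k"];
  s.tors = as<IntegerMatrix>(sys["tors"]);
  s.tor_n = sys["tor_n"]; s.tor_phase = sys["tor_phase"]; s.tor_v = sys["tor_v"];
  s.pairs = as<IntegerMatrix>(sys["pairs"]);
  s.pr_sig = sys["pr_sig"]; s.pr_eps = sys["pr_eps"];
  s.pr_qq = sys["pr_qq"]; s.pr_scale = sys["pr_scale"];
  s.cutoff = as<double>(sys["cutoff"]);
  return s;
}

static double ff_forces(const NumericMatrix& X, const Sys& s, NumericMatrix& F,
                        NumericVector& terms) {
  double e_bond = 0, e_ang = 0, e_tor = 0, e_lj = 0, e_coul = 0;
  for (int b = 0; b < s.bonds.nrow(); ++b) {
    int i = s.bonds(b, 0), j = s.bonds(b, 1);
    V3 d = getr(X, i) - getr(X, j);
    double r = nrm(d);
    if (r < 1e-8) stop("coincident bonded atoms");
    double dr = r - s.bond_r0[b];
    e_bond += 0.5 * s.bond_k[b] * dr * dr;
    V3 f = (-s.bond_k[b] * dr / r) * d;
    addf(F, i, f); addf(F, j, -1.0 * f);
  }
  for (int a = 0; a < s.angles.nrow(); ++a) {
    int i = s.angles(a, 0), j = s.angles(a, 1), k = s.angles(a, 2);
    V3 u = getr(X, i) - getr(X, j);
    V3 v = getr(X, k) - getr(X, j);
    double lu = nrm(u), lv = nrm(v);
    double ct = dot(u, v) / (lu * lv);
    ct = std::max(-1.0, std::min(1.0, ct));
    double st = std::sqrt(std::max(1e-14, 1.0 - ct * ct));
    double th = std::acos(ct);
    double dE = s.ang_k[a] * (th - s.ang_th0[a]);
    e_ang += 0.5 * s.ang_k[a] * (th - s.ang_th0[a]) * (th - s.ang_th0[a]);
    // dtheta/du = -(v_hat - ct*u_hat)/(|u| st)
    V3 uh = (1.0 / lu) * u, vh = (1.0 / lv) * v;
    V3 gi = (-1.0 / (lu * st)) * (vh - ct * uh);
    V3 gk = (-1.0 / (lv * st)) * (uh - ct * vh);
    V3 fi = -dE * gi, fk = -dE * gk;
    addf(F, i, fi); addf(F, k, fk); addf(F, j, -1.0 * (fi + fk));
  }
  for (int t = 0; t < s.tors.nrow(); ++t) {
    V3 g[4];
    int i = s.tors(t, 0), j = s.tors(t, 1), k = s.tors(t, 2), l = s.tors(t, 3);
    double phi = dihedral(X, i, j, k, l, g, true);
    int nn = s.tor_n[t];
    double arg = nn * phi - s.tor_phase[t];
    e_tor += 0.5 * s.tor_v[t] * (1.0 + std::cos(arg));
    double dE = -0.5 * s.tor_v[t] * nn * std::sin(arg);
    addf(F, i, -dE * g[0]); addf(F, j, -dE * g[1]);
    addf(F, k, -dE * g[2]); addf(F, l, -dE * g[3]);
  }
  double cut2 = s.cutoff * s.cutoff;
  for (int p = 0; p < s.pairs.nrow(); ++p) {
    int i = s.pairs(p, 0), j = s.pairs(p, 1);
    V3 d = getr(X, i) - getr(X, j);
    double r2 = dot(d, d);
    if (r2 > cut2) continue;
    double r = std::sqrt(r2);
    if (r < 0.1) stop("nonbonded singularity: atoms closer than 0.1 A");
    double sc = s.pr_scale[p];
    double sr2 = s.pr_sig[p] * s.pr_sig[p] / r2;
    double sr6 = sr2 * sr2 * sr2;
    double elj = sc * 4.0 * s.pr_eps[p] * (sr6 * sr6 - sr6);
    double ecl = sc * s.pr_qq[p] / r;
    e_lj += elj; e_coul += ecl;
    // -dE/dr
    double fr = sc * (4.0 * s.pr_eps[p] * (12.0 * sr6 * sr6 - 6.0 * sr6) / r) + ecl / r;
    V3 f = (fr / r) * d;
    addf(F, i, f); addf(F, j, -1.0 * f);
  }
  terms[0] = e_bond; terms[1] = e_ang; terms[2] = e_tor;
  terms[3] = e_lj; terms[4] = e_coul;
  return e_bond + e_ang + e_tor + e_lj + e_coul;
}

// [[Rcpp::export]]
List cpp_ff(const NumericMatrix& x, const List& sys) {
  Sys s = unpack_sys(sys);
  NumericMatrix F(s.n, 3);
  NumericVector terms(5);
  terms.names() = CharacterVector::create("bond", "angle", "torsion", "lj", "coulomb");
  double e = ff_forces(x, s, F, terms);
  return List::create(_["energy"] = e, _["forces"] = F, _["terms"] = terms);
}

// ---------------------------------------------------------------------------
// constraint machinery
// ---------------------------------------------------------------------------
struct Cons {
  // RDC (each row: up to three C-H/H-H pairs; nprot = 1 or 3)
  IntegerMatrix rdc_idx;   // nr x 6
  IntegerVector rdc_np;
  NumericVector rdc_dmax, rdc_dexp, rdc_dD;
  // NOE (methyl constraints pre-expanded to single pairs sharing a target)
  IntegerMatrix noe_idx;   // ni x 2
  NumericVector noe_rexp, noe_dr;
  // 3J
  IntegerMatrix j_idx;     // nj x 4
  NumericVector j_jexp, j_dD;
  NumericMatrix j_P;       // nj x 6 (P6 in radians)
  NumericMatrix j_chi, j_xi; // nj x 4
  IntegerVector j_ns;
};

static Cons unpack_cons(const List& cons) {
  Cons c;
  c.rdc_idx = as<IntegerMatrix>(cons["rdc_idx"]);
  c.rdc_np = cons["rdc_np"];
  c.rdc_dmax = cons["rdc_dmax"]; c.rdc_dexp = cons["rdc_dexp"]; c.rdc_dD = cons["rdc_dD"];
  c.noe_idx = as<IntegerMatrix>(cons["noe_idx"]);
  c.noe_rexp = cons["noe_rexp"]; c.noe_dr = cons["noe_dr"];
  c.j_idx = as<IntegerMatrix>(cons["j_idx"]);
  c.j_jexp = cons["j_jexp"]; c.j_dD = cons["j_dD"];
  c.j_P = as<NumericMatrix>(cons["j_P"]);
  c.j_chi = as<NumericMatrix>(cons["j_chi"]); c.j_xi = as<NumericMatrix>(cons["j_xi"]);
  c.j_ns = cons["j_ns"];
  return c;
}

// lab-frame dipolar tensor of one internuclear unit vector, row-major 3x3
static void lab_tensor9(V3 u, double dmax, double* t) {
  double uu[3] = { u.x, u.y, u.z };
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b)
      t[3 * a + b] = dmax * (1.5 * uu[a] * uu[b] - 0.5 * (a == b));
}

// instantaneous RDC observable (averaged over methyl protons where needed)
static void rdc_observable(const NumericMatrix& X, const Cons& c, int r, double* t9) {
  for (int q = 0; q < 9; ++q) t9[q] = 0.0;
  int np = c.rdc_np[r];
  double tt[9];
  for (int h = 0; h < np; ++h) {
    int i = c.rdc_idx(r, 2 * h), j = c.rdc_idx(r, 2 * h + 1);
    V3 d = getr(X, i) - getr(X, j);
    double rr = nrm(d);
    if (rr < 1e-8) stop("zero-length internuclear vector in RDC constraint");
    lab_tensor9((1.0 / rr) * d, c.rdc_dmax[r], tt);
    for (int q = 0; q < 9; ++q) t9[q] += tt[q] / np;
  }
}

// pseudo-force of one RDC constraint given its memory-mean tensor M (9)
static void rdc_force_one(const NumericMatrix& X, const Cons& c, int r,
                          const double* M, double kf, NumericMatrix& F) {
  double E[9] = { -0.5 * c.rdc_dexp[r], 0, 0, 0, -0.5 * c.rdc_dexp[r], 0, 0, 0, c.rdc_dexp[r] };
  double f[9];
  for (int q = 0; q < 9; ++q) f[q] = std::tanh((M[q] - E[q]) / c.rdc_dD[r]);
  int np = c.rdc_np[r];
  double w = kf / np;
  for (int h = 0; h < np; ++h) {
    int i = c.rdc_idx(r, 2 * h), j = c.rdc_idx(r, 2 * h + 1);
    V3 d = getr(X, i) - getr(X, j);
    double rr = nrm(d);
    if (rr < 1e-8) stop("zero-length internuclear vector in RDC constraint");
    V3 u = (1.0 / rr) * d;
    double uu[3] = { u.x, u.y, u.z };
    double g[3];
    for (int a = 0; a < 3; ++a) {
      g[a] = 0.0;
      for (int b = 0; b < 3; ++b) g[a] += f[3 * a + b] * uu[b];
      g[a] *= 3.0 * c.rdc_dmax[r];
    }
    V3 gv = v3(g[0], g[1], g[2]);
    V3 gperp = gv - dot(gv, u) * u;        // orientational derivative only
    V3 fi = (-w / rr) * gperp;
    addf(F, i, fi); addf(F, j, -1.0 * fi);
  }
}

static double karplus_eval(double phi, const double* P, const double* chi,
                           const double* xi, int ns, double* dJ) {
  double cp = std::cos(phi), sp = std::sin(phi);
  double J = P[0] * cp * cp + P[1] * cp + P[2];
  double d = -2.0 * P[0] * cp * sp - P[1] * sp;
  for (int s = 0; s < ns; ++s) {
    double a = xi[s] * phi + P[5] * std::fabs(chi[s]);
    double ca = std::cos(a);
    J += chi[s] * (P[3] + P[4] * ca * ca);
    d += chi[s] * P[4] * (-2.0 * ca * std::sin(a)) * xi[s];
  }
  *dJ = d;
  return J;
}

// add all pseudo-forces; memory means supplied (S/N); kf already includes ramp
static void pseudo_forces(const NumericMatrix& X, const Cons& c,
                          const NumericMatrix& rdc_S, const NumericVector& rdc_N,
                          const NumericVector& noe_S, const NumericVector& noe_N,
                          const NumericVector& j_S, const NumericVector& j_N,
                          double k_rdc, double k_noe, double k_j,
                          NumericMatrix& F) {
  for (int r = 0; r < c.rdc_idx.nrow(); ++r) {
    if (rdc_N[r] <= 0) continue;
    double M[9];
    for (int q = 0; q < 9; ++q) M[q] = rdc_S(r, q) / rdc_N[r];
    rdc_force_one(X, c, r, M, k_rdc, F);
  }
  for (int p = 0; p < c.noe_idx.nrow(); ++p) {
    if (noe_N[p] <= 0) continue;
    double rbar = std::pow(noe_S[p] / noe_N[p], -1.0 / 6.0);
    int i = c.noe_idx(p, 0), j = c.noe_idx(p, 1);
    V3 d = getr(X, i) - getr(X, j);
    double rr = nrm(d);
    if (rr < 1e-8) stop("coincident protons in NOE constraint");
    double f = std::tanh((rbar - c.noe_rexp[p]) / c.noe_dr[p]);
    V3 fi = (-k_noe * f / rr) * d;   // attractive when rbar > target
    addf(F, i, fi); addf(F, j, -1.0 * fi);
  }
  for (int t = 0; t < c.j_idx.nrow(); ++t) {
    if (j_N[t] <= 0) continue;
    double Jm = j_S[t] / j_N[t];
    V3 g[4];
    double phi = dihedral(X, c.j_idx(t, 0), c.j_idx(t, 1), c.j_idx(t, 2), c.j_idx(t, 3), g, true);
    double dJ;
    double P[6], chi[4], xi[4];
    for (int q = 0; q < 6; ++q) P[q] = c.j_P(t, q);
    for (int q = 0; q < 4; ++q) { chi[q] = c.j_chi(t, q); xi[q] = c.j_xi(t, q); }
    karplus_eval(phi, P, chi, xi, c.j_ns[t], &dJ);
    double f = std::tanh((Jm - c.j_jexp[t]) / c.j_dD[t]);
    double coef = -k_j * f * dJ;
    for (int a = 0; a < 4; ++a) addf(F, c.j_idx(t, a), coef * g[a]);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_pseudo_forces(const NumericMatrix& x, const List& cons,
                                const NumericMatrix& rdc_S, const NumericVector& rdc_N,
                                const NumericVector& noe_S, const NumericVector& noe_N,
                                const NumericVector& j_S, const NumericVector& j_N,
                                double k_rdc, double k_noe, double k_j) {
  Cons c = unpack_cons(cons);
  NumericMatrix F(x.nrow(), 3);
  pseudo_forces(x, c, rdc_S, rdc_N, noe_S, noe_N, j_S, j_N, k_rdc, k_noe, k_j, F);
  return F;
}

// [[Rcpp::export]]
NumericVector cpp_karplus(const NumericVector& phi, const NumericVector& P,
                          const NumericVector& chi, const NumericVector& xi) {
  int ns = chi.size();
  if (ns > 4) stop("at most 4 substituents supported");
  double Pa[6], ca[4] = {0, 0, 0, 0}, xa[4] = {1, 1, 1, 1};
  for (int q = 0; q < 6; ++q) Pa[q] = P[q];
  for (int q = 0; q < ns; ++q) { ca[q] = chi[q]; xa[q] = xi[q]; }
  NumericVector out(phi.size());
  double dJ;
  for (int q = 0; q < phi.size(); ++q)
    out[q] = karplus_eval(phi[q], Pa, ca, xa, ns, &dJ);
  return out;
}

// [[Rcpp::export]]
List cpp_rdc_observables(const NumericMatrix& x, const List& cons) {
  Cons c = unpack_cons(cons);
  int nr = c.rdc_idx.nrow();
  NumericMatrix out(nr, 9);
  double t9[9];
  for (int r = 0; r < nr; ++r) {
    rdc_observable(x, c, r, t9);
    for (int q = 0; q < 9; ++q) out(r, q) = t9[q];
  }
  return List::create(_["tensors"] = out);
}

// ---------------------------------------------------------------------------
// MDOC main loop: velocity Verlet + Berendsen weak coupling + memory updates
// ---------------------------------------------------------------------------
static double kinetic(const NumericMatrix& V, const NumericVector& m) {
  double ke = 0;
  for (int i = 0; i < V.nrow(); ++i)
    ke += m[i] * (V(i, 0) * V(i, 0) + V(i, 1) * V(i, 1) + V(i, 2) * V(i, 2));
  return 0.5 * KE2KJ * ke;
}

// [[Rcpp::export]]
List cpp_run_mdoc(NumericMatrix x0, NumericMatrix v0, const List& sys,
                  const List& cons, const List& cfg) {
  Sys s = unpack_sys(sys);
  Cons c = unpack_cons(cons);
  int n = s.n;
  NumericMatrix X = clone(x0), V = clone(v0);

  double dt = as<double>(cfg["dt"]);
  int nsteps = as<int>(cfg["nsteps"]);
  int drop_steps = as<int>(cfg["drop_steps"]);
  int snap_every = as<int>(cfg["snap_every"]);
  double temp = as<double>(cfg["temp"]);
  double tau_t = as<double>(cfg["tau_t"]);
  double tau = as<double>(cfg["tau"]);
  double rho = as<double>(cfg["rho"]);
  double k_rdc = as<double>(cfg["k_rdc"]);
  double k_noe = as<double>(cfg["k_noe"]);
  double k_j = as<double>(cfg["k_j"]);
  bool thermostat = as<bool>(cfg["thermostat"]);
  bool record_log = as<bool>(cfg["record_log"]);

  int nr = c.rdc_idx.nrow(), ni = c.noe_idx.nrow(), nj = c.j_idx.nrow();
  NumericMatrix rdc_S(nr, 9); NumericVector rdc_N(nr);
  NumericVector noe_S(ni), noe_N(ni), j_S(nj), j_N(nj);
  double decay = std::exp(-dt / tau);

  int ndof = 3 * n - 3;
  NumericVector terms(5);

  // per-step observable log (short diagnostic runs only)
  NumericMatrix log_rdc, log_noe, log_j;
  if (record_log) {
    log_rdc = NumericMatrix(nsteps, nr * 9);
    log_noe = NumericMatrix(nsteps, ni);
    log_j = NumericMatrix(nsteps, nj);
  }

  if (snap_every <= 0) snap_every = nsteps + 1;   // no snapshots
  int nsnap_max = nsteps / snap_every + 1;
  std::vector<double> snap_t; snap_t.reserve(nsnap_max);
  std::vector<double> snap_e; snap_e.reserve(nsnap_max);
  List snap_x(nsnap_max);
  NumericMatrix snap_rdc(nsnap_max, nr * 9);
  NumericMatrix snap_noe(nsnap_max, ni);
  NumericMatrix snap_j(nsnap_max, nj);
  int nsnap = 0;

  NumericMatrix F(n, 3);
  double epot = ff_forces(X, s, F, terms);
  // memory empty at start: no pseudo-forces on the very first evaluation

  double t9[9];
  for (int step = 1; step <= nsteps; ++step) {
    double t = step * dt;
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt * F2A / s.mass[i];
      V(i, 0) += h * F(i, 0); V(i, 1) += h * F(i, 1); V(i, 2) += h * F(i, 2);
      X(i, 0) += dt * V(i, 0); X(i, 1) += dt * V(i, 1); X(i, 2) += dt * V(i, 2);
    }
    // forces at new coordinates; pseudo magnitudes use means of previous step
    std::fill(F.begin(), F.end(), 0.0);
    epot = ff_forces(X, s, F, terms);
    double ramp = 1.0 - std::exp(-t / rho);
    pseudo_forces(X, c, rdc_S, rdc_N, noe_S, noe_N, j_S, j_N,
                  ramp * k_rdc, ramp * k_noe, ramp * k_j, F);
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt * F2A / s.mass[i];
      V(i, 0) += h * F(i, 0); V(i, 1) += h * F(i, 1); V(i, 2) += h * F(i, 2);
    }
    // blow-up guard
    for (int i = 0; i < n; ++i)
      for (int q = 0; q < 3; ++q)
        if (!std::isfinite(X(i, q)) || std::fabs(X(i, q)) > 1e5) {
          double fn = std::sqrt(F(i, 0) * F(i, 0) + F(i, 1) * F(i, 1) + F(i, 2) * F(i, 2));
          stop("MDOC blow-up at step %d (t = %g ps): atom %d non-finite or runaway, |F| = %g",
               step, t, i + 1, fn);
        }
    if (thermostat) {
      double tins = 2.0 * kinetic(V, s.mass) / (ndof * KB);
      if (tins > 1e-12) {
        double lam = std::sqrt(1.0 + (dt / tau_t) * (temp / tins - 1.0));
        lam = std::max(0.8, std::min(1.25, lam));
        for (int i = 0; i < n; ++i) {
          V(i, 0) *= lam; V(i, 1) *= lam; V(i, 2) *= lam;
        }
      }
    }
    // memory update with instantaneous observables at the new coordinates
    for (int r = 0; r < nr; ++r) {
      rdc_observable(X, c, r, t9);
      rdc_N[r] = rdc_N[r] * decay + dt;
      for (int q = 0; q < 9; ++q) {
        rdc_S(r, q) = rdc_S(r, q) * decay + t9[q] * dt;
        if (record_log) log_rdc(step - 1, r * 9 + q) = t9[q];
      }
    }
    for (int p = 0; p < ni; ++p) {
      int i = c.noe_idx(p, 0), j = c.noe_idx(p, 1);
      V3 d = getr(X, i) - getr(X, j);
      double rr = nrm(d);
      if (rr < 1e-8) stop("coincident protons in NOE constraint");
      double r6 = std::pow(rr, -6.0);
      noe_N[p] = noe_N[p] * decay + dt;
      noe_S[p] = noe_S[p] * decay + r6 * dt;
      if (record_log) log_noe(step - 1, p) = r6;
    }
    for (int tq = 0; tq < nj; ++tq) {
      V3 g[4];
      double phi = dihedral(X, c.j_idx(tq, 0), c.j_idx(tq, 1), c.j_idx(tq, 2),
                            c.j_idx(tq, 3), g, false);
      double dJ, P[6], chi[4], xi[4];
      for (int q = 0; q < 6; ++q) P[q] = c.j_P(tq, q);
      for (int q = 0; q < 4; ++q) { chi[q] = c.j_chi(tq, q); xi[q] = c.j_xi(tq, q); }
      double Jv = karplus_eval(phi, P, chi, xi, c.j_ns[tq], &dJ);
      j_N[tq] = j_N[tq] * decay + dt;
      j_S[tq] = j_S[tq] * decay + Jv * dt;
      if (record_log) log_j(step - 1, tq) = Jv;
    }
    // snapshot
    if (step > drop_steps && step % snap_every == 0) {
      snap_t.push_back(t);
      snap_e.push_back(epot);
      snap_x[nsnap] = clone(X);
      for (int r = 0; r < nr; ++r)
        for (int q = 0; q < 9; ++q)
          snap_rdc(nsnap, r * 9 + q) = rdc_S(r, q) / rdc_N[r];
      for (int p = 0; p < ni; ++p)
        snap_noe(nsnap, p) = std::pow(noe_S[p] / noe_N[p], -1.0 / 6.0);
      for (int tq = 0; tq < nj; ++tq)
        snap_j(nsnap, tq) = j_S[tq] / j_N[tq];
      ++nsnap;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  List snaps(nsnap);
  for (int q = 0; q < nsnap; ++q) snaps[q] = snap_x[q];
  NumericMatrix out_rdc(nsnap, nr * 9), out_noe(nsnap, ni), out_j(nsnap, nj);
  for (int q = 0; q < nsnap; ++q) {
    for (int w = 0; w < nr * 9; ++w) out_rdc(q, w) = snap_rdc(q, w);
    for (int w = 0; w < ni; ++w) out_noe(q, w) = snap_noe(q, w);
    for (int w = 0; w < nj; ++w) out_j(q, w) = snap_j(q, w);
  }
  List out = List::create(
    _["times"] = wrap(snap_t),
    _["coords"] = snaps,
    _["energies"] = wrap(snap_e),
    _["rdc_mean"] = out_rdc,
    _["noe_mean"] = out_noe,
    _["j_mean"] = out_j,
    _["x_final"] = X, _["v_final"] = V,
    _["mem"] = List::create(_["rdc_S"] = rdc_S, _["rdc_N"] = rdc_N,
                            _["noe_S"] = noe_S, _["noe_N"] = noe_N,
                            _["j_S"] = j_S, _["j_N"] = j_N));
  if (record_log)
    out["log"] = List::create(_["rdc"] = log_rdc, _["noe"] = log_noe, _["j"] = log_j);
  return out;
}

// single velocity-Verlet step on plain force field (exposed for unit tests)
// [[Rcpp::export]]
List cpp_verlet_steps(NumericMatrix x0, NumericMatrix v0, const List& sys,
                      double dt, int nsteps, bool thermostat, double temp,
                      double tau_t) {
  Sys s = unpack_sys(sys);
  int n = s.n;
  NumericMatrix X = clone(x0), V = clone(v0);
  NumericVector terms(5);
  NumericMatrix F(n, 3);
  double epot = ff_forces(X, s, F, terms);
  NumericVector etot(nsteps), ekin(nsteps);
  int ndof = 3 * n - 3;
  for (int step = 0; step < nsteps; ++step) {
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt * F2A / s.mass[i];
      V(i, 0) += h * F(i, 0); V(i, 1) += h * F(i, 1); V(i, 2) += h * F(i, 2);
      X(i, 0) += dt * V(i, 0); X(i, 1) += dt * V(i, 1); X(i, 2) += dt * V(i, 2);
    }
    std::fill(F.begin(), F.end(), 0.0);
    epot = ff_forces(X, s, F, terms);
    for (int i = 0; i < n; ++i) {
      double h = 0.5 * dt * F2A / s.mass[i];
      V(i, 0) += h * F(i, 0); V(i, 1) += h * F(i, 1); V(i, 2) += h * F(i, 2);
    }
    double ke = kinetic(V, s.mass);
    if (thermostat && ke > 1e-12) {
      double tins = 2.0 * ke / (ndof * KB);
      double lam = std::sqrt(1.0 + (dt / tau_t) * (temp / tins - 1.0));
      lam = std::max(0.8, std::min(1.25, lam));
      for (int i = 0; i < n; ++i) {
        V(i, 0) *= lam; V(i, 1) *= lam; V(i, 2) *= lam;
      }
      ke = kinetic(V, s.mass);
    }
    ekin[step] = ke;
    etot[step] = ke + epot;
    for (int i = 0; i < n; ++i)
      for (int q = 0; q < 3; ++q)
        if (!std::isfinite(X(i, q)))
          stop("integration blow-up at step %d: atom %d non-finite", step + 1, i + 1);
  }
  return List::create(_["x"] = X, _["v"] = V, _["etot"] = etot, _["ekin"] = ekin);
}
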