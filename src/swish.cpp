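// Coarse-grained peptide model: internal-coordinate builder, energy with a
// linearly lambda-scalable solvent-dispersion term, and Metropolis sweeps.
// Atom layout per residue r (0-based): r == 0 -> N, CA, C, O, SC (no amide H
// on the first residue); r >= 1 -> N, H, CA, C, O, SC. Energies in kcal/mol,
// lengths in Angstrom, angles in degrees.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;
static const double COULOMB = 332.0637;  // kcal A / (mol e^2)

// Ideal internal geometry (Angstrom / degrees).
static const double B_N_CA = 1.458, B_CA_C = 1.525, B_C_N = 1.329;
static const double B_C_O = 1.231, B_N_H = 1.0;
static const double A_N_CA_C = 111.2, A_CA_C_N = 116.2, A_C_N_CA = 121.7;
static const double A_CA_C_O = 120.8, A_N_CA_SC = 110.5;
static const double T_C_N_CA_SC = -120.0;  // improper fixing SC chirality

inline int natoms_for(int L) { return 6 * L - 1; }
inline int idxN(int r)  { return r == 0 ? 0 : 5 + 6 * (r - 1); }
inline int idxH(int r)  { return 5 + 6 * (r - 1) + 1; }  // r >= 1 only
inline int idxCA(int r) { return r == 0 ? 1 : 5 + 6 * (r - 1) + 2; }
inline int idxC(int r)  { return r == 0 ? 2 : 5 + 6 * (r - 1) + 3; }
inline int idxO(int r)  { return r == 0 ? 3 : 5 + 6 * (r - 1) + 4; }
inline int idxSC(int r) { return r == 0 ? 4 : 5 + 6 * (r - 1) + 5; }

struct V3 { double x, y, z; };
inline V3 sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline V3 add(const V3& a, const V3& b) { return {a.x+b.x, a.y+b.y, a.z+b.z}; }
inline V3 scale(const V3& a, double s) { return {a.x*s, a.y*s, a.z*s}; }
inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline V3 cross(const V3& a, const V3& b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }
inline V3 unit(const V3& a) { double n = norm(a); return {a.x/n, a.y/n, a.z/n}; }

// Natural extension reference frame: place D bonded to C with |C-D| = bond,
// angle(B,C,D) = ang and torsion(A,B,C,D) = tors.
static V3 nerf(const V3& A, const V3& B, const V3& C,
               double bond, double ang, double tors) {
  double th = ang * DEG, ph = tors * DEG;
  V3 bc = unit(sub(C, B));
  V3 ab = sub(B, A);
  V3 n = unit(cross(ab, bc));
  V3 m = cross(n, bc);
  double dx = -bond * std::cos(th);
  double dy = bond * std::sin(th) * std::cos(ph);
  double dz = bond * std::sin(th) * std::sin(ph);
  return {C.x + dx*bc.x + dy*m.x + dz*n.x,
          C.y + dx*bc.y + dy*m.y + dz*n.y,
          C.z + dx*bc.z + dy*m.z + dz*n.z};
}

static void build_coords(const std::vector<double>& phi,
                         const std::vector<double>& psi,
                         const std::vector<double>& sc_dist,
                         std::vector<V3>& X) {
  int L = phi.size();
  X.resize(natoms_for(L));
  // First residue in the canonical frame.
  X[idxN(0)] = {0.0, 0.0, 0.0};
  X[idxCA(0)] = {B_N_CA, 0.0, 0.0};
  double alpha = (180.0 - A_N_CA_C) * DEG;
  X[idxC(0)] = {B_N_CA + B_CA_C * std::cos(alpha), B_CA_C * std::sin(alpha), 0.0};
  X[idxO(0)] = nerf(X[idxN(0)], X[idxCA(0)], X[idxC(0)],
                    B_C_O, A_CA_C_O, psi[0] + 180.0);
  if (sc_dist[0] > 0)
    X[idxSC(0)] = nerf(X[idxC(0)], X[idxN(0)], X[idxCA(0)],
                       sc_dist[0], A_N_CA_SC, T_C_N_CA_SC);
  else
    X[idxSC(0)] = X[idxCA(0)];
  for (int r = 1; r < L; ++r) {
    X[idxN(r)] = nerf(X[idxN(r-1)], X[idxCA(r-1)], X[idxC(r-1)],
                      B_C_N, A_CA_C_N, psi[r-1]);
    X[idxCA(r)] = nerf(X[idxCA(r-1)], X[idxC(r-1)], X[idxN(r)],
                       B_N_CA, A_C_N_CA, 180.0);
    X[idxC(r)] = nerf(X[idxC(r-1)], X[idxN(r)], X[idxCA(r)],
                      B_CA_C, A_N_CA_C, phi[r]);
    X[idxO(r)] = nerf(X[idxN(r)], X[idxCA(r)], X[idxC(r)],
                      B_C_O, A_CA_C_O, psi[r] + 180.0);
    if (sc_dist[r] > 0)
      X[idxSC(r)] = nerf(X[idxC(r)], X[idxN(r)], X[idxCA(r)],
                         sc_dist[r], A_N_CA_SC, T_C_N_CA_SC);
    else
      X[idxSC(r)] = X[idxCA(r)];
    // Amide H opposes the preceding carbonyl (DSSP-style reconstruction).
    V3 d = unit(sub(X[idxC(r-1)], X[idxO(r-1)]));
    X[idxH(r)] = add(X[idxN(r)], scale(d, B_N_H));
  }
}

struct SysPar {
  std::vector<int> kind;      // 0 N, 1 H, 2 CA, 3 C, 4 O, 5 SC
  std::vector<int> res;       // 0-based residue of each atom
  std::vector<double> q, eps, sigma;
  std::vector<int> apolar;    // lambda-coupled flag per atom
  std::vector<double> sc_dist;
  // torsion basins
  std::vector<double> c_phi, c_psi, width;
  NumericMatrix depth;        // L x n_basins
  double dielectric, debye_length, s_apolar, cutoff_exposure, hardcore;
  int n_max, L;
};

static SysPar unpack(const List& sys) {
  SysPar p;
  p.kind = as<std::vector<int> >(sys["kind"]);
  p.res = as<std::vector<int> >(sys["res"]);
  p.q = as<std::vector<double> >(sys["q"]);
  p.eps = as<std::vector<double> >(sys["eps"]);
  p.sigma = as<std::vector<double> >(sys["sigma"]);
  p.apolar = as<std::vector<int> >(sys["apolar"]);
  p.sc_dist = as<std::vector<double> >(sys["sc_dist"]);
  p.c_phi = as<std::vector<double> >(sys["basin_phi"]);
  p.c_psi = as<std::vector<double> >(sys["basin_psi"]);
  p.width = as<std::vector<double> >(sys["basin_width"]);
  p.depth = as<NumericMatrix>(sys["basin_depth"]);
  p.dielectric = as<double>(sys["dielectric"]);
  p.debye_length = as<double>(sys["debye_length"]);
  p.s_apolar = as<double>(sys["s_apolar"]);
  p.cutoff_exposure = as<double>(sys["cutoff_exposure"]);
  p.hardcore = as<double>(sys["hardcore"]);
  p.n_max = as<int>(sys["n_max"]);
  p.L = p.sc_dist.size();
  return p;
}

// periodic wrap to [-180, 180) without libm fmod
inline double wrap180(double d) {
  return d - 360.0 * std::floor((d + 180.0) / 360.0);
}
inline double ang_diff(double a, double b) { return wrap180(a - b); }

static double torsion_energy(const std::vector<double>& phi,
                             const std::vector<double>& psi, const SysPar& p) {
  double e = 0.0;
  int nb = p.c_phi.size();
  for (int r = 0; r < p.L; ++r) {
    for (int b = 0; b < nb; ++b) {
      double dphi = ang_diff(phi[r], p.c_phi[b]);
      double dpsi = ang_diff(psi[r], p.c_psi[b]);
      double w2 = 2.0 * p.width[b] * p.width[b];
      e -= p.depth(r, b) * std::exp(-(dphi*dphi + dpsi*dpsi) / w2);
    }
  }
  return e;
}

// Returns (torsion, lj, elec, W, clash). U0 = torsion + lj + elec.
static void energy_terms(const std::vector<V3>& X,
                         const std::vector<double>& phi,
                         const std::vector<double>& psi,
                         const SysPar& p, double out[5]) {
  int n = X.size();
  std::vector<int> nc(n, 0);
  double lj = 0.0, elec = 0.0;
  bool clash = false;
  double cut2 = p.cutoff_exposure * p.cutoff_exposure;
  double hc2 = p.hardcore * p.hardcore;
  for (int a = 0; a < n; ++a) {
    if (p.kind[a] == 1) continue;               // H excluded from energetics
    for (int b = a + 1; b < n; ++b) {
      if (p.kind[b] == 1) continue;
      int dr = p.res[b] - p.res[a]; if (dr < 0) dr = -dr;
      if (dr == 0) continue;
      V3 d = sub(X[a], X[b]);
      double r2 = dot(d, d);
      if (dr >= 2) {
        if (r2 < cut2) { nc[a]++; nc[b]++; }  // non-local burial contacts
        if (r2 < hc2) clash = true;
        bool beadA = (p.kind[a] == 2 || p.kind[a] == 5);
        bool beadB = (p.kind[b] == 2 || p.kind[b] == 5);
        if (beadA && beadB) {
          double eps = std::sqrt(p.eps[a] * p.eps[b]);
          if (eps > 0) {
            double sig = 0.5 * (p.sigma[a] + p.sigma[b]);
            double s2 = sig * sig / r2;
            double s6 = s2 * s2 * s2;
            lj += 4.0 * eps * (s6 * s6 - s6);
          }
        }
      }
      double qq = p.q[a] * p.q[b];
      if (qq != 0.0) {
        double r = std::sqrt(r2);
        elec += COULOMB * qq / (p.dielectric * r) * std::exp(-r / p.debye_length);
      }
    }
  }
  double W = 0.0;
  for (int a = 0; a < n; ++a) {
    if (p.apolar[a]) {
      double expo = p.n_max - nc[a];
      if (expo > 0) W -= p.s_apolar * expo;
    }
  }
  out[0] = torsion_energy(phi, psi, p);
  out[1] = lj;
  out[2] = elec;
  out[3] = W;
  out[4] = clash ? 1.0 : 0.0;
}

static NumericMatrix to_matrix(const std::vector<V3>& X) {
  NumericMatrix m(X.size(), 3);
  for (size_t i = 0; i < X.size(); ++i) {
    m(i, 0) = X[i].x; m(i, 1) = X[i].y; m(i, 2) = X[i].z;
  }
  return m;
}

// [[Rcpp::export]]
NumericMatrix cpp_build_coords(NumericVector phi, NumericVector psi,
                               NumericVector sc_dist) {
  std::vector<double> ph = as<std::vector<double> >(phi);
  std::vector<double> ps = as<std::vector<double> >(psi);
  std::vector<double> sd = as<std::vector<double> >(sc_dist);
  std::vector<V3> X;
  build_coords(ph, ps, sd, X);
  return to_matrix(X);
}

// [[Rcpp::export]]
NumericVector cpp_energy_terms(NumericVector phi, NumericVector psi, List sys) {
  SysPar p = unpack(sys);
  std::vector<double> ph = as<std::vector<double> >(phi);
  std::vector<double> ps = as<std::vector<double> >(psi);
  std::vector<V3> X;
  build_coords(ph, ps, p.sc_dist, X);
  double t[5];
  energy_terms(X, ph, ps, p, t);
  double U0 = t[4] > 0 ? R_PosInf : t[0] + t[1] + t[2];
  return NumericVector::create(_["U0"] = U0, _["W"] = t[3],
                               _["torsion"] = t[0], _["lj"] = t[1],
                               _["elec"] = t[2], _["clash"] = t[4]);
}

// [[Rcpp::export]]
NumericVector cpp_exposure(NumericVector phi, NumericVector psi, List sys) {
  SysPar p = unpack(sys);
  std::vector<double> ph = as<std::vector<double> >(phi);
  std::vector<double> ps = as<std::vector<double> >(psi);
  std::vector<V3> X;
  build_coords(ph, ps, p.sc_dist, X);
  int n = X.size();
  std::vector<int> nc(n, 0);
  double cut2 = p.cutoff_exposure * p.cutoff_exposure;
  for (int a = 0; a < n; ++a) {
    if (p.kind[a] == 1) continue;
    for (int b = a + 1; b < n; ++b) {
      if (p.kind[b] == 1) continue;
      int dr = p.res[b] - p.res[a]; if (dr < 0) dr = -dr;
      if (dr < 2) continue;
      V3 d = sub(X[a], X[b]);
      if (dot(d, d) < cut2) { nc[a]++; nc[b]++; }
    }
  }
  NumericVector out(n);
  for (int a = 0; a < n; ++a)
    out[a] = p.apolar[a] ? std::max(0.0, double(p.n_max - nc[a])) : NA_REAL;
  return out;
}

// One or more Metropolis sweeps over all phi/psi angles at fixed lambda.
// Uses R's RNG stream (caller controls seeding). Records dihedrals and
// energies at global sweep counts divisible by `record_every` (0 = no
// recording); `record_offset` is the global sweep count before this block.
// [[Rcpp::export]]
List cpp_mc_block(NumericVector phi, NumericVector psi, List sys,
                  double lambda, double kT, double delta_max,
                  int n_sweeps, int record_every, int record_offset) {
  SysPar p = unpack(sys);
  std::vector<double> ph = as<std::vector<double> >(phi);
  std::vector<double> ps = as<std::vector<double> >(psi);
  int L = p.L;
  std::vector<V3> X, Xtrial;
  build_coords(ph, ps, p.sc_dist, X);
  double t[5];
  energy_terms(X, ph, ps, p, t);
  bool cur_clash = t[4] > 0;
  double U0 = t[0] + t[1] + t[2], W = t[3];
  int n_acc = 0, n_moves = 0;
  int n_rec = record_every > 0 ?
    (record_offset + n_sweeps) / record_every - record_offset / record_every : 0;
  NumericMatrix rec_phi(n_rec, L), rec_psi(n_rec, L);
  NumericVector rec_U0(n_rec), rec_W(n_rec);
  int ri = 0;
  std::vector<double> pht = ph, pst = ps;
  for (int sw = 0; sw < n_sweeps; ++sw) {
    for (int r = 0; r < L; ++r) {
      for (int which = 0; which < 2; ++which) {
        double old_ang = which == 0 ? ph[r] : ps[r];
        double prop = old_ang + (2.0 * unif_rand() - 1.0) * delta_max;
        prop = wrap180(prop);
        if (prop <= -180.0) prop = 180.0;
        pht = ph; pst = ps;
        if (which == 0) pht[r] = prop; else pst[r] = prop;
        build_coords(pht, pst, p.sc_dist, Xtrial);
        double tt[5];
        energy_terms(Xtrial, pht, pst, p, tt);
        bool trial_clash = tt[4] > 0;
        double U0t = tt[0] + tt[1] + tt[2], Wt = tt[3];
        bool accept;
        if (trial_clash) {
          accept = false;
        } else if (cur_clash) {
          accept = true;  // escaping an infinite-energy state
        } else {
          double dU = (U0t + lambda * Wt) - (U0 + lambda * W);
          accept = dU <= 0.0 || unif_rand() < std::exp(-dU / kT);
        }
        ++n_moves;
        if (accept) {
          ++n_acc;
          ph = pht; ps = pst; X = Xtrial;
          U0 = U0t; W = Wt; cur_clash = trial_clash;
        }
      }
    }
    if (record_every > 0 && (record_offset + sw + 1) % record_every == 0 &&
        ri < n_rec) {
      for (int r = 0; r < L; ++r) { rec_phi(ri, r) = ph[r]; rec_psi(ri, r) = ps[r]; }
      rec_U0[ri] = cur_clash ? R_PosInf : U0;
      rec_W[ri] = W;
      ++ri;
    }
  }
  return List::create(
    _["phi"] = NumericVector(ph.begin(), ph.end()),
    _["psi"] = NumericVector(ps.begin(), ps.end()),
    _["U0"] = cur_clash ? R_PosInf : U0, _["W"] = W,
    _["n_accepted"] = n_acc, _["n_moves"] = n_moves,
    _["rec_phi"] = rec_phi, _["rec_psi"] = rec_psi,
    _["rec_U0"] = rec_U0, _["rec_W"] = rec_W);
}
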